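# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

toy_refs <- function() cached("refs", function() build_toy_references(seed = 42))

# clean library: pure C|A cleavage, no sequencing errors
clean_library <- function() cached("clean_lib", function() {
  simulate_library(toy_refs(),
                   simulator_config(seed = 7, n_reads = 3000,
                                    p_ca_cleavage = 1, error_rate = 0))
})

# realistic library: default generator world
noisy_library <- function() cached("noisy_lib", function() {
  simulate_library(toy_refs(), simulator_config(seed = 11, n_reads = 5000))
})

clean_assignments <- function() cached("clean_aln", function() {
  lib <- clean_library()
  pre <- preprocess_reads(lib$reads)
  map_sequential(pre$reads, toy_refs())
})

noisy_assignments <- function() cached("noisy_aln", function() {
  lib <- noisy_library()
  pre <- preprocess_reads(lib$reads)
  map_sequential(pre$reads, toy_refs())
})

# reference sequences as a plain named character vector
ref_seq_list <- function(refs = toy_refs()) {
  unlist(lapply(cp_categories(), function(cat_)
    setNames(as.character(refs$categories[[cat_]]),
             names(refs$categories[[cat_]]))))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}
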