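# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

# 4 hosts (2 EV, 1 GTA, 1 transducer) + 2 free viruses
small_community <- function() fixture("small_com", {
  build_community(
    n_hosts = 4, n_viruses = 2,
    mechanism_counts = c(EV_producer = 2, GTA_producer = 1, transducer = 1),
    genome_len_range = c(110e3, 140e3), seed = 7)
})

small_pedna <- function() fixture("small_pedna", {
  sample_pedna_reads(small_community(), default_pedna_mix(),
                     n_pairs = 8000, seed = 3)
})

# host-only contig table of the small community
small_mags <- function() {
  com <- small_community()
  community_contigs(com)[com$role == "host", ]
}
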