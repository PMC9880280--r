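# Shared, lazily built fixtures. Expensive simulations are cached so that
# several tests (and the acceptance suite) can reuse the same runs.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

default_net <- function() cached("default_net", build_network(seed = 1))

spike_run <- function(b, seed) {
  cached(sprintf("spikes_b%d_s%d", b, seed),
         simulate_spiking(default_net(), adex_params(b = b),
                          duration = 5000, seed = seed))
}

spike_class <- function(b, seed) {
  cached(sprintf("cls_b%d_s%d", b, seed),
         classify_state(population_rate(spike_run(b, seed)),
                        transient = 1000))
}

syn_conn <- function() cached("conn68",
                              generate_synthetic_connectome(68, seed = 42))

brain_run <- function(b, conn = syn_conn(), seed = 1, tag = "") {
  cached(sprintf("brain_b%d_s%d%s", b, seed, tag),
         simulate_brain(brain_config(conn, b = b, duration = 10000,
                                     seed = seed)))
}

small_conn <- function() cached("conn8",
                                generate_synthetic_connectome(8, seed = 3))

# independent brute-force LZ parser (dictionary as a plain character
# vector, sequential word growth) used as the oracle for lempel_ziv()
lz_bruteforce <- function(bits) {
  dict <- character(0)
  word <- ""
  for (ch in bits) {
    word <- paste0(word, ch)
    if (!(word %in% dict)) {
      dict <- c(dict, word)
      word <- ""
    }
  }
  length(dict) + as.integer(nzchar(word))
}

# all binary vectors of length n
all_bitstrings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}
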