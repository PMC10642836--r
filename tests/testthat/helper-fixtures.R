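# Small deterministic fixtures built in code.

tiny_codeset <- function(n_end = 4, n_hk = 2, n_pos = 6, n_neg = 4) {
  codeset(
    code_class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                     c(n_end, n_hk, n_pos, n_neg)),
    name = c(sprintf("G%02d", seq_len(n_end)), sprintf("HK%02d", seq_len(n_hk)),
             paste0("POS_", LETTERS[seq_len(n_pos)]),
             paste0("NEG_", LETTERS[seq_len(n_neg)])),
    expected_concentration = c(rep(NA, n_end + n_hk),
                               128 / 4^(seq_len(n_pos) - 1), rep(NA, n_neg))
  )
}

# count matrix with controllable positive-control geometric means and
# constant negatives; endogenous/housekeeping values supplied per lane
tiny_matrix <- function(pos_gm = c(100, 100, 100), neg = 10,
                        end = NULL, hk = 50, n_end = 4, n_hk = 2) {
  n <- length(pos_gm)
  cs <- tiny_codeset(n_end = n_end, n_hk = n_hk)
  if (is.null(end)) end <- matrix(100, n_end, n)
  if (!is.matrix(end)) end <- matrix(end, n_end, n)
  if (!is.matrix(hk)) hk <- matrix(hk, n_hk, n)
  vals <- rbind(end, hk,
                matrix(rep(pos_gm, each = 6), 6, n),
                matrix(neg, 4, n))
  rownames(vals) <- cs$name
  colnames(vals) <- paste0("S", seq_len(n))
  count_matrix(vals, cs, raw = all(vals == round(vals)))
}

# cached default simulated cohort shared across test files
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(sim_config(seed = 101))
      norm <- normalize_pipeline(ds$counts)
      de <- run_de(norm$matrix, ds$annotations, norm$noise_calls)
      cache <<- list(ds = ds, norm = norm, de = de)
    }
    cache
  }
})
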