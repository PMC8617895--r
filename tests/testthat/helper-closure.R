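# In-memory simulate -> detect loop shared by the detection-closure and
# end-to-end recovery tests: generates pulling cycles, runs the detection
# chain, and returns detected vs true rupture forces.

simulate_and_detect <- function(cfg, n_cycles, seed) {
  set.seed(seed)
  rows <- vector("list", 2L * n_cycles)
  k <- 0L
  for (cyc in seq_len(n_cycles)) {
    gu <- generate_fdc_trace(cfg, "unfold", cycle_id = cyc)
    gf <- generate_fdc_trace(cfg, "fold", cycle_id = cyc)
    baseline <- fit_folded_baseline(median_filter(gu$trace, 11L))
    for (g in list(gu, gf)) {
      ft <- detect_event(g, cfg, baseline)
      k <- k + 1L
      rows[[k]] <- data.frame(
        direction = g$truth$direction,
        true_force = if (g$truth$has_event) g$truth$true_force else NA_real_,
        detected_force = ft$force_pN,
        censored = ft$censored
      )
    }
  }
  do.call(rbind, rows)
}
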