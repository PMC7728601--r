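# Shared evaluation of ancestry-painting recovery on a simulated diploid
# mosaic (fast observation path).
evaluate_mosaic_recovery <- function(seed, genome_length = 1e7,
                                     thresholds = classification_thresholds()) {
  cfg <- simulation_config(genome_length = genome_length, seed = seed)
  truth <- simulate_mosaic_truth(cfg)
  obs <- simulate_window_observations(truth, cfg)
  paint <- list()
  true_org <- list()
  for (h in c("A", "B")) {
    p <- paint_haplome(obs[obs$haplome == h, ], thresholds)
    th <- truth[truth$haplome == h, ]
    true_org[[h]] <- intersect_regions_with_ancestry(
      p$windows[, c("chrom", "start", "end")], th)$origin
    paint[[h]] <- p
  }
  s <- summarize_painting(paint$A, paint$B)
  calls <- rbind(
    data.frame(call = paint$A$windows$call, truth = true_org$A),
    data.frame(call = paint$B$windows$call, truth = true_org$B)
  )
  classifiable <- calls$call != "unclear"
  list(
    n_classifiable = sum(classifiable),
    n_correct = sum(calls$call[classifiable] == calls$truth[classifiable]),
    truth_hybrid = mean(true_org$A != true_org$B),
    est_hybrid = s$diploid[["hybrid"]],
    summary = s
  )
}
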