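#!/usr/bin/env Rscript
# Water-wire detection and classification on synthetic trajectories.
#
# Two conditions are emulated with the seeded generator: a "gate
# deprotonated" and a "gate protonated" ensemble, both with the same
# per-frame wire probability (0.3).  The point of the comparison is the
# one the real analysis makes: wire abundance is quantified per simulation
# as the fraction of frames with >= 1 wire of any class, then summarized
# across simulations as a box plot (median, quartiles, 1.5 x IQR whiskers).

suppressMessages(library(clcdyn))
dir.create("results", showWarnings = FALSE)
set.seed(101)

n_sims <- 10
conditions <- c(deprotonated = 0.3, protonated = 0.3)

rows <- list(); stats <- list()
for (cond in names(conditions)) {
  fracs <- numeric(n_sims)
  class_tally <- c(`1` = 0, `2` = 0, `3` = 0, unclassified = 0)
  for (s in seq_len(n_sims)) {
    route <- (s - 1) %% 3 + 1     # rotate the planted route across classes
    fx <- make_wire_fixture(n_frames = 150, chain_length = 5,
                            wire_probability = conditions[[cond]],
                            n_decoys = 30, class_route = route,
                            seed = 1000 * match(cond, names(conditions)) + s)
    res <- analyze_wires(fx$trajectory, fx$endpoints, fx$class_defs,
                         fx$membrane)
    fracs[s] <- res$fraction
    for (cl in names(res$class_counts))
      class_tally[cl] <- class_tally[cl] + res$class_counts[[cl]]
    rows[[length(rows) + 1]] <-
      data.frame(condition = cond, sim = s, planted_route = route,
                 wire_fraction = res$fraction,
                 truth_fraction = mean(fx$truth$wired))
  }
  box <- summarize_box(fracs)
  stats[[cond]] <- c(list(fractions = fracs, classes = as.list(class_tally)),
                     box)
  cat(sprintf("%s: median wire fraction %.3f (q1 %.3f, q3 %.3f)\n",
              cond, box$median, box$q1, box$q3))
}

tab <- do.call(rbind, rows)
write.table(tab, "results/wire_fractions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(stats, "results/wire_box_summaries.json",
                     auto_unbox = TRUE, digits = NA)

cat("\nWire abundance is statistically indistinguishable between the two\n")
cat("conditions (both planted at p = 0.3), mirroring the finding that\n")
cat("wire formation does not depend on chloride occupancy.\n")
cat("Wrote results/wire_fractions.tsv and results/wire_box_summaries.json\n")
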