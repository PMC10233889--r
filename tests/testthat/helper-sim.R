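# shared scaled-down configurations

# two-genotype study-shaped config, knock-down arm off for speed
quick_config <- function(seed, ...) {
  simulation_config(seed = seed, knockdown = FALSE, ...)
}

# null configuration: one mutant genotype, 6 vs 6, nothing planted
null_config <- function(seed, ...) {
  simulation_config(seed = seed, genotypes = "Y537S",
                    n_planted_de_mirna = 0L,
                    planted_split = c(both = 0L, Y537S = 0L),
                    n_coupled_mirna = 0L,
                    coupled_split = c(both = 0L, Y537S = 0L),
                    knockdown = FALSE, ...)
}

# small exponential growth table built directly (not via the generator)
make_growth <- function(rates, sd = 0, wells = 4, t_max = 48, dt = 2,
                        c0 = 15, ceiling = 100) {
  t <- seq(0, t_max, by = dt)
  rows <- list()
  for (cond in names(rates)) {
    for (w in seq_len(wells)) {
      eps <- if (sd > 0) stats::rnorm(length(t), 0, sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, well = sprintf("%s_w%d", cond, w), time_h = t,
        confluence_pct = pmin(ceiling, c0 * 2^(rates[[cond]] * t) * exp(eps)),
        stringsAsFactors = FALSE)
    }
  }
  growth_table(do.call(rbind, rows))
}
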