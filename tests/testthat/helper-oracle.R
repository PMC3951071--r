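# Independent dense grid-search oracle for the bounded LQ fit: coarse pass over
# a in [0, 0.3] x b in [0, 0.01], then a refined pass (steps 1e-4 / 1e-5)
# around the coarse optimum. Works purely by objective evaluation.
grid_search_lq <- function(dose, fraction, weights = rep(1, length(dose)),
                           a_max = 0.3, b_max = 0.01) {
  ssr_grid <- function(a_vals, b_vals) {
    g <- expand.grid(a = a_vals, b = b_vals)
    ssr <- numeric(nrow(g))
    for (i in seq_along(dose)) {
      ssr <- ssr + weights[i] *
        (fraction[i] - exp(-g$a * dose[i] - g$b * dose[i]^2))^2
    }
    g[which.min(ssr), ]
  }
  coarse <- ssr_grid(seq(0, a_max, by = 1e-3), seq(0, b_max, by = 1e-4))
  fine <- ssr_grid(
    seq(max(coarse$a - 2e-3, 0), min(coarse$a + 2e-3, a_max), by = 1e-4),
    seq(max(coarse$b - 2e-4, 0), min(coarse$b + 2e-4, b_max), by = 1e-5))
  c(a = fine$a, b = fine$b)
}
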