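# Stand-alone deep-loess trajectory: the loess ledger driven directly by the
# permafrost model, without the classifier stages.

#' Deep-loess carbon trajectory for a world
#'
#' Runs the loess ledger over all millennia, thawing regions as their cells
#' leave each model's continuous-permafrost mask. Equivalent to the loess
#' component of [run_reconstruction()].
#'
#' @param world A [build_world()] object.
#' @param params Permafrost parameters ([default_permafrost_params()]).
#' @param retention Fraction of thawed C retained.
#' @return data.frame `time_ka`, `stock_pg`, `sd_pg`, `loss_pg`.
#' @export
loess_trajectory <- function(world, params = default_permafrost_params(),
                             retention = world$scenario$retention_on_thaw) {
  st <- loess_init(world$loess, world$domain)
  s0 <- loess_summary(st)
  out <- data.frame(time_ka = 21, stock_pg = s0$stock_pg,
                    sd_pg = s0$sd_pg, loss_pg = 0)
  for (t in 20:0) {
    cont <- lapply(stats::setNames(nm = model_labels()), function(m)
      permafrost_map(world, m, t, params)$continuous)
    st <- loess_step(st, cont, t, retention = retention)
    out <- rbind(out, data.frame(time_ka = t, stock_pg = st$stock_pg,
                                 sd_pg = st$sd_pg, loss_pg = st$loss_pg))
  }
  out
}
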