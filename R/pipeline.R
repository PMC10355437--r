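#' Run the full study pipeline
#'
#' End-to-end orchestration: build (or accept) a connectome, stabilise the
#' intact network, run the lesion sweep, and collect the per-lesion summary
#' table plus the excitability analyses. Every random draw is derived from
#' one master seed, so reruns with the same configuration are identical.
#'
#' @param config either a named list or a path to a YAML file with (all
#'   optional) entries: `n_regions`, `connectome_seed`, `decay_length`,
#'   `density`, `homotopic_boost`, `C`, `rho`, `mean_delay`, `record_s`,
#'   `max_stab_s`, `lesion_nodes` (indices; default: the 2 strongest nodes),
#'   `seed`.
#' @param connectome optional pre-built [connectome()] overriding the
#'   synthetic generator.
#' @return object of class `stroke_study`: `connectome`, `config` (resolved),
#'   `baseline` (`wc_steady`), `sweep`, `summary` (per-lesion data frame),
#'   `correlations` ([lesion_correlations()] output when >= 3 lesions),
#'   `average_map`.
#' @export
run_study <- function(config = list(), connectome = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(n_regions = 16, connectome_seed = 1, decay_length = 40,
                   density = 0.5, homotopic_boost = 3,
                   C = 4.07, rho = 0.2, mean_delay = 4,
                   record_s = 300, max_stab_s = 3000,
                   lesion_nodes = NULL, seed = 1)
  cfg_list <- utils::modifyList(defaults, config)
  c <- if (!is.null(connectome)) connectome
       else synth_connectome(n_regions = cfg_list$n_regions,
                             decay_length = cfg_list$decay_length,
                             density = cfg_list$density,
                             homotopic_boost = cfg_list$homotopic_boost,
                             seed = cfg_list$connectome_seed)
  wc <- wc_config(C = cfg_list$C, rho = cfg_list$rho,
                  mean_delay = cfg_list$mean_delay, seed = cfg_list$seed)
  nodes <- cfg_list$lesion_nodes
  if (is.null(nodes)) nodes <- order(node_strength(c), decreasing = TRUE)[1:2]
  baseline <- stabilize(wc, c, max_duration_s = cfg_list$max_stab_s,
                        seed = derive_seed(cfg_list$seed, 0))
  sweep <- sweep_lesions(wc, c, nodes, baseline,
                         record_s = cfg_list$record_s,
                         max_stab_s = cfg_list$max_stab_s,
                         seed = cfg_list$seed)
  ok <- Filter(function(e) inherits(e, "lesion_experiment"), sweep)
  summ <- do.call(rbind, lapply(ok, summary))
  corr <- if (length(ok) >= 3) lesion_correlations(sweep, c) else NULL
  avg <- if (length(ok) >= 1) sweep_average_map(sweep, c) else NULL
  structure(list(connectome = c, config = cfg_list, wc_config = wc,
                 baseline = baseline, sweep = sweep, summary = summ,
                 correlations = corr, average_map = avg),
            class = "stroke_study")
}

#' @export
print.stroke_study <- function(x, ...) {
  cat("Stroke lesion study:", x$connectome$n, "regions,",
      nrow(x$summary), "lesions\n")
  cat(sprintf("  baseline stabilization: %s\n",
              if (x$baseline$converged)
                sprintf("converged at %.0f s", x$baseline$time_s)
              else "capped"))
  if (nrow(x$summary)) {
    cat(sprintf("  FC distance to baseline: T1 median %.3f -> T2 median %.3f\n",
                stats::median(x$summary$fc_dist_T1),
                stats::median(x$summary$fc_dist_T2)))
    cat(sprintf("  mean delta c_EI: %.3f%% (negative = net excitability increase)\n",
                mean(x$summary$mean_delta_cei_pct)))
  }
  invisible(x)
}

#' Plot a lesion experiment
#'
#' Two-panel base-graphics display: FC matrices at T0/T1/T2 and the
#' excitability-change map against distance to the lesion.
#'
#' @param x a `lesion_experiment`.
#' @param ... unused.
#' @export
plot.lesion_experiment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (tp in c("T0", "T1", "T2")) {
    fc <- unclass(static_fc(x$records[[tp]]$bold))
    graphics::image(fc, zlim = c(-1, 1), col = pal, axes = FALSE,
                    main = paste("FC", tp))
  }
  dmap <- delta_cei(x)
  d <- euclidean_distances(x$connectome_intact)[, x$node]
  graphics::plot(d, dmap$delta_cei_pct, xlab = "distance to lesion (mm)",
                 ylab = expression(Delta * c[EI] ~ "(%)"),
                 main = "excitability change", pch = 19)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
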