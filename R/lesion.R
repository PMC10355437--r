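#' Run the three-phase stroke protocol for one lesion
#'
#' Implements the in-silico stroke timeline on a connectome whose inhibitory
#' weights have already converged (`baseline`):
#' \enumerate{
#'   \item \strong{T0} (pre-lesion baseline): record with plasticity off on
#'     the intact connectome at the converged weights.
#'   \item Lesion: all connections to and from `node` are removed.
#'   \item \strong{T1} (acute): record with plasticity still off - the
#'     network has lost input but inhibition is unadapted.
#'   \item Re-stabilisation: plasticity on until the weights reach a new
#'     steady state (or `max_stab_s` is hit, flagged).
#'   \item \strong{T2} (chronic): record with plasticity off at the new
#'     weights.
#' }
#' Plasticity is always disabled during the three recordings so measured
#' activity is not confounded by weight drift.
#'
#' @param cfg a [wc_config()].
#' @param c the intact [connectome()].
#' @param node lesioned region (index or label).
#' @param baseline a `wc_steady` from [stabilize()] on the intact connectome
#'   (its state seeds all runs), or a bare steady-state `c_EI` vector.
#' @param record_s duration of each recording, s (default 300; the full-scale
#'   protocol uses 1800).
#' @param max_stab_s cap on post-lesion re-stabilisation, s (default 3000;
#'   full scale 30000).
#' @param discard_s transient discarded before each recording, s.
#' @param hemo a [hemo_config()] for the BOLD transform.
#' @param seed RNG seed for this experiment (default derived from
#'   `cfg$seed`).
#' @param keep_rates keep the decimated rate series in the result (needed for
#'   avalanche metrics; default TRUE).
#' @return object of class `lesion_experiment`: `node`, `records` (list
#'   `T0`/`T1`/`T2`, each with `bold` (filtered [bold_record()]) and
#'   optionally `rates`), `cei_T0`, `cei_T2`, `convergence_time_s`,
#'   `converged`, `connectome` (lesioned), `connectome_intact`.
#' @export
run_protocol <- function(cfg, c, node, baseline, record_s = 300,
                         max_stab_s = 3000, discard_s = 10,
                         hemo = hemo_config(), seed = cfg$seed,
                         keep_rates = TRUE) {
  stopifnot(inherits(cfg, "wc_config"), inherits(c, "connectome"))
  node <- resolve_region(c, node)
  cei0 <- if (inherits(baseline, "wc_steady")) baseline$cei else as.double(baseline)
  stopifnot(length(cei0) == c$n)

  make_record <- function(conn, init, sd) {
    sim <- simulate_wc(cfg, conn, record_s, plasticity = FALSE, init = init,
                       discard_s = discard_s, seed = sd)
    bold <- bold_bandpass(bold_transform(sim, hemo), hemo)
    list(bold = bold, rates = if (keep_rates) sim$rE else NULL,
         mean_rE = rowMeans(sim$rE), state = sim$state)
  }

  t0 <- make_record(c, cei0, derive_seed(seed, 1))
  lesioned <- apply_lesion(c, node)
  t1 <- make_record(lesioned, cei0, derive_seed(seed, 2))
  st <- stabilize(cfg, lesioned, init_cei = cei0, max_duration_s = max_stab_s,
                  seed = derive_seed(seed, 3))
  t2 <- make_record(lesioned, st$cei, derive_seed(seed, 4))

  records <- list(T0 = t0, T1 = t1, T2 = t2)
  structure(list(node = node, label = c$regions$label[node],
                 records = records,
                 cei_T0 = cei0, cei_T2 = st$cei,
                 convergence_time_s = st$time_s, converged = st$converged,
                 connectome = lesioned, connectome_intact = c,
                 record_s = record_s, seed = seed),
            class = "lesion_experiment")
}

#' @export
print.lesion_experiment <- function(x, ...) {
  cat("Lesion experiment: node", x$node, paste0("('", x$label, "')"), "\n")
  cat(sprintf("  re-convergence: %s%s\n",
              if (x$converged) sprintf("%.0f s simulated", x$convergence_time_s)
              else "not reached (capped)",
              if (x$converged) "" else " [T2 flagged]"))
  fc0 <- static_fc(x$records$T0$bold)
  cat(sprintf("  FC distance to baseline: T1 %.3f, T2 %.3f (lesioned node excluded)\n",
              fc_distance(static_fc(x$records$T1$bold), fc0, exclude = x$node),
              fc_distance(static_fc(x$records$T2$bold), fc0, exclude = x$node)))
  invisible(x)
}

#' Summary metrics of a lesion experiment
#'
#' Computes the standard per-lesion readouts: FC distance of T1 and T2 from
#' baseline (lesioned node excluded by default), FC-SC correlation, synchrony
#' and metastability, avalanche criticality k, and the across-density mean
#' modularity and small-world coefficients normalised to T0.
#'
#' @param object a `lesion_experiment`.
#' @param partition module partition on the full region set (default:
#'   consensus modules from the T0 FC).
#' @param include_lesioned include the lesioned node in FC distance and FC-SC
#'   correlation (default FALSE).
#' @param q_densities,sw_densities,n_random see [lesion_graph_metrics()];
#'   defaults here are desk-scale (fewer random graphs).
#' @param ... unused.
#' @return a one-row data frame of class `summary.lesion_experiment`.
#' @export
summary.lesion_experiment <- function(object, partition = NULL,
                                      include_lesioned = FALSE,
                                      q_densities = seq(0.04, 0.40, by = 0.02),
                                      sw_densities = seq(0.20, 0.40, by = 0.02),
                                      n_random = 20, ...) {
  x <- object
  excl <- if (include_lesioned) NULL else x$node
  fc <- lapply(x$records, function(r) static_fc(r$bold))
  if (is.null(partition))
    partition <- consensus_modules(fc$T0, seed = derive_seed(x$seed, 99))
  gm <- lapply(seq_along(fc), function(i)
    lesion_graph_metrics(fc[[i]], partition, lesioned_node = x$node,
                         q_densities = q_densities,
                         sw_densities = sw_densities,
                         n_random = n_random, seed = derive_seed(x$seed, 10 + i)))
  names(gm) <- names(fc)
  dyn <- lapply(x$records, function(r)
    synchrony_metastability(kuramoto_series(r$bold)))
  kcrit <- vapply(x$records, function(r) {
    if (is.null(r$rates)) return(NA_real_)
    criticality_k(detect_avalanches(r$rates))
  }, numeric(1))
  d_cei <- delta_cei(x)
  out <- data.frame(
    node = x$node, label = x$label,
    strength = node_strength(x$connectome_intact)[x$node],
    fc_dist_T1 = fc_distance(fc$T1, fc$T0, exclude = excl),
    fc_dist_T2 = fc_distance(fc$T2, fc$T0, exclude = excl),
    fc_sc_T0 = fc_sc_correlation(fc$T0, x$connectome_intact, exclude = excl),
    fc_sc_T1 = fc_sc_correlation(fc$T1, x$connectome_intact, exclude = excl),
    fc_sc_T2 = fc_sc_correlation(fc$T2, x$connectome_intact, exclude = excl),
    q_T0 = gm$T0$mean_q, q_T1 = gm$T1$mean_q, q_T2 = gm$T2$mean_q,
    sw_T0 = gm$T0$mean_sw, sw_T1 = gm$T1$mean_sw, sw_T2 = gm$T2$mean_sw,
    sync_T0 = dyn$T0[["synchrony"]], sync_T1 = dyn$T1[["synchrony"]],
    sync_T2 = dyn$T2[["synchrony"]],
    meta_T0 = dyn$T0[["metastability"]], meta_T1 = dyn$T1[["metastability"]],
    meta_T2 = dyn$T2[["metastability"]],
    k_T0 = kcrit[["T0"]], k_T1 = kcrit[["T1"]], k_T2 = kcrit[["T2"]],
    mean_delta_cei_pct = mean(d_cei$delta_cei_pct, na.rm = TRUE),
    convergence_time_s = x$convergence_time_s,
    converged = x$converged,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("summary.lesion_experiment", class(out))
  out
}

#' Sweep the lesion protocol over several nodes
#'
#' Runs [run_protocol()] independently for each node, with per-lesion RNG
#' seeds derived from `(seed, node)` so the sweep is reproducible and
#' parallelisable; per-lesion failures are isolated and reported.
#'
#' @param cfg,c,baseline,record_s,max_stab_s,hemo,keep_rates see
#'   [run_protocol()].
#' @param nodes region indices (or labels) to lesion.
#' @param seed master seed.
#' @return list of class `lesion_sweep` holding one `lesion_experiment` (or a
#'   `try-error`) per node.
#' @export
sweep_lesions <- function(cfg, c, nodes, baseline, record_s = 300,
                          max_stab_s = 3000, hemo = hemo_config(),
                          seed = cfg$seed, keep_rates = TRUE) {
  exps <- lapply(nodes, function(nd) {
    tryCatch(
      run_protocol(cfg, c, nd, baseline, record_s = record_s,
                   max_stab_s = max_stab_s, hemo = hemo,
                   seed = derive_seed(seed, resolve_region(c, nd)),
                   keep_rates = keep_rates),
      error = function(e) {
        warning("lesion of node ", nd, " failed: ", conditionMessage(e))
        e
      })
  })
  names(exps) <- as.character(nodes)
  class(exps) <- "lesion_sweep"
  exps
}

#' @export
print.lesion_sweep <- function(x, ...) {
  ok <- vapply(x, inherits, logical(1), "lesion_experiment")
  cat("Lesion sweep:", sum(ok), "of", length(x), "experiments completed\n")
  invisible(x)
}

#' Mirror per-region values so the lesioned hemisphere is fixed
#'
#' For lesions in the left hemisphere, swaps each region's value with its
#' homotopic partner so that in pooled maps the same side is always
#' ipsilesional (convention: right = ipsilesional). Right-hemisphere lesions
#' pass through unchanged. Regions without a homotope keep their value.
#' Applying the mirror twice is the identity.
#'
#' @param values per-region numeric vector.
#' @param lesioned_node region index of the lesion.
#' @param c a [connectome()] (supplies hemisphere flags and the homotope
#'   map).
#' @return mirrored numeric vector.
#' @export
mirror_to_ipsilesional <- function(values, lesioned_node, c) {
  stopifnot(inherits(c, "connectome"), length(values) == c$n)
  if (c$regions$hemisphere[lesioned_node] == "R") return(values)
  out <- values
  has <- which(!is.na(c$homotope))
  out[has] <- values[c$homotope[has]]
  out
}
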