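## Locus rarefaction: how do average node support, tracked-clade supports
## and node counts above fixed thresholds change as randomly drawn loci are
## added?  Pools grow in increments (default 5 loci); each pool size is
## drawn repeatedly (default 20 draws); each draw is concatenated,
## bootstrapped with the tree backend, and summarised.

#' Rarefaction configuration
#'
#' @param increment Pool-size step in loci (default 5, the study design).
#' @param n_draws Random draws per pool size (default 20).
#' @param thresholds Support thresholds for node counting (strict `>`).
#' @param n_reps Bootstrap replicates per draw.
#' @param model Distance model for the tree backend.
#' @param codon_aware Resample codon triplets in the bootstrap.
#' @param master_seed Master seed; per-draw seeds are derived as
#'   `derive_seed(master_seed, pool_size, draw)` so curves are extensible
#'   without re-running earlier sizes.
#' @return List of class `rarefaction_config`.
#' @export
rarefaction_config <- function(increment = 5, n_draws = 20,
                               thresholds = c(50, 70, 90), n_reps = 100,
                               model = "p", codon_aware = FALSE,
                               master_seed = 1L) {
  structure(list(increment = increment, n_draws = n_draws,
                 thresholds = thresholds, n_reps = n_reps, model = model,
                 codon_aware = codon_aware,
                 master_seed = as.integer(master_seed)),
            class = "rarefaction_config")
}

#' Draw a locus subset for one rarefaction draw
#'
#' Uniform sampling without replacement; deterministic given
#' `(master_seed, pool_size, draw_index)`.
#'
#' @param locus_ids All locus identifiers.
#' @param pool_size Number of loci to draw (<= total).
#' @param draw_index Draw number within the pool size.
#' @param master_seed Master seed.
#' @return Character vector of `pool_size` distinct locus ids.
#' @export
subsample_loci <- function(locus_ids, pool_size, draw_index, master_seed) {
  if (pool_size > length(locus_ids))
    stop("pool_size exceeds the number of loci")
  set.seed(derive_seed(master_seed, pool_size, draw_index))
  sample(locus_ids, pool_size)
}

#' Run a rarefaction analysis over curated alignments
#'
#' For each pool size (multiples of the increment up to the total locus
#' count, with the full pool always included) and each draw: the drawn loci
#' are concatenated over the shared taxon set, bootstrap support is
#' estimated with the distance backend, and average node support, tracked
#' clade supports and node counts above the thresholds are recorded.
#'
#' @param curated_alignments Named list of character matrices or
#'   `curation_result`s (one per locus).
#' @param clades List of [clade_definition()]s to track (may be empty).
#' @param config A [rarefaction_config()].
#' @param taxon_universe Row set for concatenation; default the union over
#'   loci.
#' @param verbose Print progress per pool size.
#' @return A `rarefaction_curve`: `draws` (tidy data frame: pool_size, draw,
#'   mean_support, one column per tracked clade, n_gt<th> per threshold),
#'   `summary` (across-draw mean and SD of mean support per pool size),
#'   `config`.
#' @export
run_rarefaction <- function(curated_alignments, clades = list(),
                            config = rarefaction_config(),
                            taxon_universe = NULL, verbose = FALSE) {
  mats <- lapply(curated_alignments, function(x)
    if (inherits(x, "curation_result")) x$alignment else x)
  loci <- names(mats)
  stopifnot(length(loci) >= 3)
  if (is.null(taxon_universe))
    taxon_universe <- sort(unique(unlist(lapply(mats, rownames))))
  total <- length(loci)
  sizes <- seq(config$increment, total, by = config$increment)
  if (length(sizes) == 0 || sizes[length(sizes)] != total)
    sizes <- c(sizes, total)
  clade_names <- vapply(clades, `[[`, character(1), "name")

  rows <- list()
  for (ps in sizes) {
    failed <- 0L
    for (dr in seq_len(config$n_draws)) {
      subset_ids <- subsample_loci(loci, ps, dr, config$master_seed)
      ## canonical order, and a content-derived bootstrap seed: identical
      ## subsets give identical results (so the full pool has zero
      ## across-draw spread), while distinct subsets get distinct streams
      subset_ids <- loci[loci %in% subset_ids]
      sm <- concatenate(mats[subset_ids], taxon_universe = taxon_universe)
      st <- tryCatch(
        bootstrap_support(sm$matrix, n_reps = config$n_reps,
                          seed = derive_seed(config$master_seed, "boot",
                                             paste(subset_ids,
                                                   collapse = ",")),
                          model = config$model,
                          codon_aware = config$codon_aware),
        error = function(e) NULL)
      if (is.null(st)) { failed <- failed + 1L; next }
      rec <- data.frame(pool_size = ps, draw = dr,
                        mean_support = average_node_support(st))
      for (i in seq_along(clades))
        rec[[clade_names[i]]] <- clade_support(st, clades[[i]])
      for (th in config$thresholds)
        rec[[paste0("n_gt", th)]] <- count_nodes_above(st, th)
      rows[[length(rows) + 1L]] <- rec
    }
    if (failed > config$n_draws / 2)
      stop("pool size ", ps, ": more than half of the draws failed")
    if (verbose)
      message("pool size ", ps, " done (", failed, " failed draws)")
  }
  draws <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(draws, draws$pool_size), function(d)
    data.frame(pool_size = d$pool_size[1], n_draws = nrow(d),
               mean_support = mean(d$mean_support),
               sd_support = stats::sd(d$mean_support))))
  summ <- summ[order(summ$pool_size), ]
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, config = config),
            class = "rarefaction_curve")
}

#' Detect the plateau of a rarefaction curve
#'
#' Returns the smallest pool size from which every subsequent across-draw
#' mean stays strictly within `tolerance` of its running mean over the
#' trailing `window` values (windows clipped at the candidate start).
#'
#' @param curve A `rarefaction_curve`, or a numeric vector of across-draw
#'   means ordered by pool size.
#' @param window Trailing window length in pool sizes.
#' @param tolerance Maximum deviation in support points.
#' @return The plateau pool size (or index, for a bare numeric series), or
#'   `NA` when the series never settles.
#' @export
plateau_detect <- function(curve, window = 3, tolerance = 2) {
  if (inherits(curve, "rarefaction_curve")) {
    x <- curve$summary$mean_support
    sizes <- curve$summary$pool_size
  } else {
    x <- as.numeric(curve)
    sizes <- seq_along(x)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 pool sizes")
  for (i in seq_len(n - window + 1)) {
    ok <- TRUE
    for (j in i:n) {
      lo <- max(i, j - window + 1)
      if (abs(x[j] - mean(x[lo:j])) >= tolerance) { ok <- FALSE; break }
    }
    if (ok) return(sizes[i])
  }
  NA_real_
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("Rarefaction curve:", nrow(x$summary), "pool sizes,",
      x$config$n_draws, "draws each\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot a rarefaction curve
#'
#' Mean support versus pool size with an across-draw +/- 1 SD envelope;
#' tracked clades, when present, are overlaid as dashed lines.
#'
#' @param x A `rarefaction_curve`.
#' @param ... Passed to `plot`.
#' @export
plot.rarefaction_curve <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$pool_size, s$mean_support, type = "b", pch = 16,
                 xlab = "Number of loci", ylab = "Average node support (%)",
                 ylim = c(0, 100), ...)
  graphics::arrows(s$pool_size, s$mean_support - s$sd_support,
                   s$pool_size, s$mean_support + s$sd_support,
                   angle = 90, code = 3, length = 0.03)
  extra <- setdiff(names(x$draws),
                   c("pool_size", "draw", "mean_support",
                     grep("^n_gt", names(x$draws), value = TRUE)))
  for (i in seq_along(extra)) {
    agg <- stats::aggregate(x$draws[[extra[i]]],
                            list(pool_size = x$draws$pool_size), mean)
    graphics::lines(agg$pool_size, agg$x, lty = 2, col = i + 1)
  }
  if (length(extra))
    graphics::legend("bottomright", legend = extra, lty = 2,
                     col = seq_along(extra) + 1, bty = "n", cex = 0.8)
  invisible(x)
}
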