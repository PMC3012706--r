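#' Phase-marker gene screens
#'
#' Two screens over the 2-phase (gregarious/solitary) x 6-stage design
#' identify candidate phase markers:
#'
#' * phase-specific: expressed (>= 1 assigned read) in at least 5 of the
#'   6 developmental stages of one phase but not expressed in at least 4
#'   stages of the other phase;
#' * stable-difference: over the 5 post-egg stages, expression is stable
#'   within each phase (coefficient of variability, sd/mean, < 0.3),
#'   the two phase means differ by more than 1.5-fold, and a two-sample
#'   t test across stages gives p < 0.05. Egg libraries are excluded.
#'
#' The printed CV rule joins the two phases with an ambiguous "or"; both
#' readings are available via `cv_mode` ("both" groups under the CV cap,
#' the default, or "either").
#'
#' @name markers
#' @keywords internal
NULL

#' Phase-specific marker screen
#'
#' @param presence Logical (or 0/1) matrix, units x libraries: detection
#'   by the assigned-count >= 1 rule.
#' @param design data.frame with columns `library`, `phase` (two levels)
#'   and `stage` (six levels); one library per phase-stage cell.
#' @param min_present,min_absent Stage-count thresholds (defaults 5 and 4
#'   of the 6 stages).
#' @return data.frame of marker calls: `unit`, `class`
#'   ("phase-specific"), `direction` (the phase expressed in), and the
#'   per-phase presence counts.
#' @export
specific_markers <- function(presence, design, min_present = 5, min_absent = 4) {
  .check_design(design, n_stages = 6)
  phases <- sort(unique(as.character(design$phase)))
  pres <- presence[, as.character(design$library), drop = FALSE] > 0
  n_present <- vapply(phases, function(ph)
    rowSums(pres[, design$phase == ph, drop = FALSE]),
    numeric(nrow(pres)))
  if (is.null(dim(n_present)))
    n_present <- matrix(n_present, nrow = 1,
                        dimnames = list(rownames(pres), phases))
  n_stages <- length(unique(design$stage))
  out <- list()
  for (i in seq_along(phases)) {
    other <- n_present[, phases[-i], drop = FALSE][, 1]
    hit <- n_present[, phases[i]] >= min_present &
      (n_stages - other) >= min_absent
    if (any(hit))
      out[[phases[i]]] <- data.frame(
        unit = rownames(presence)[hit], class = "phase-specific",
        direction = phases[i],
        n_present_target = n_present[hit, phases[i]],
        n_present_other = other[hit],
        row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(unit = character(0), class = character(0),
                      direction = character(0),
                      n_present_target = integer(0),
                      n_present_other = integer(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$unit), , drop = FALSE]
}

#' Stable-difference marker screen
#'
#' @param expr RPKM matrix, units x libraries.
#' @param design As in [specific_markers()]; the stage named by
#'   `egg_stage` is dropped before screening.
#' @param cv_max,ratio_min,alpha Thresholds (defaults 0.3, 1.5, 0.05).
#' @param cv_mode Apply the CV cap to `"both"` phase groups (default) or
#'   to at least `"either"` one.
#' @param egg_stage Stage label to exclude (default `"egg"`).
#' @return data.frame of calls with the supporting statistics (per-phase
#'   CVs and means, mean ratio, Welch t-test p); units skipped because a
#'   phase group mean was zero are listed in the `skipped` attribute.
#' @export
stable_markers <- function(expr, design, cv_max = 0.3, ratio_min = 1.5,
                           alpha = 0.05, cv_mode = c("both", "either"),
                           egg_stage = "egg") {
  cv_mode <- match.arg(cv_mode)
  design <- design[design$stage != egg_stage, , drop = FALSE]
  phases <- sort(unique(as.character(design$phase)))
  stopifnot(length(phases) == 2)
  g_libs <- as.character(design$library[design$phase == phases[1]])
  s_libs <- as.character(design$library[design$phase == phases[2]])
  if (length(g_libs) < 2 || length(s_libs) < 2)
    stop("each phase group needs at least two libraries")
  G <- expr[, g_libs, drop = FALSE]
  S <- expr[, s_libs, drop = FALSE]
  mg <- rowMeans(G); ms <- rowMeans(S)
  skipped <- rownames(expr)[mg == 0 | ms == 0]
  ok <- mg > 0 & ms > 0
  cvg <- apply(G, 1, stats::sd) / mg
  cvs <- apply(S, 1, stats::sd) / ms
  ratio <- pmax(mg, ms) / pmin(mg, ms)
  cv_ok <- if (cv_mode == "both") cvg < cv_max & cvs < cv_max
           else cvg < cv_max | cvs < cv_max
  cand <- which(ok & cv_ok & ratio > ratio_min)
  pv <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    u <- cand[i]
    pv[i] <- tryCatch(stats::t.test(G[u, ], S[u, ])$p.value,
                      error = function(e) NA_real_)
  }
  keep <- !is.na(pv) & pv < alpha
  idx <- cand[keep]
  out <- data.frame(
    unit = rownames(expr)[idx],
    class = rep("stable-difference", length(idx)),
    direction = ifelse(mg[idx] > ms[idx], phases[1], phases[2]),
    cv_g = cvg[idx], cv_s = cvs[idx],
    mean_g = mg[idx], mean_s = ms[idx],
    ratio = ratio[idx], p = pv[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out[order(out$unit), , drop = FALSE]
}

#' Run both marker screens
#'
#' @param counts Counting-unit x library matrix (detection source).
#' @param expr RPKM matrix on the same units/libraries.
#' @inheritParams stable_markers
#' @param ... Passed to the individual screens.
#' @return List with `specific`, `stable` and `overlap` (units flagged by
#'   both screens — possible on noisy data and reported, not dropped).
#' @export
screen_markers <- function(counts, expr, design, ...) {
  sp <- specific_markers(counts > 0, design)
  st <- stable_markers(expr, design, ...)
  list(specific = sp, stable = st,
       overlap = intersect(sp$unit, st$unit))
}

.check_design <- function(design, n_stages = NULL) {
  stopifnot(is.data.frame(design),
            all(c("library", "phase", "stage") %in% names(design)))
  if (length(unique(design$phase)) != 2)
    stop("design must have exactly two phases")
  if (!is.null(n_stages) && length(unique(design$stage)) != n_stages)
    stop("design must have ", n_stages, " stages")
  tab <- table(design$phase, design$stage)
  if (any(tab != 1))
    stop("design must have exactly one library per phase-stage cell")
  invisible(design)
}
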