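#' Cell viability as a percentage of the untreated control
#'
#' @param a_drug Absorbance (or equivalent activity readout) of treated
#'   wells.
#' @param a_control Absorbance of untreated control wells; must be positive.
#' @return Viability percentage(s).
#' @export
viability_percent <- function(a_drug, a_control) {
  if (any(a_control <= 0)) stop("control activity must be positive")
  a_drug / a_control * 100
}

#' Combination-versus-best-monotherapy synergy score
#'
#' From replicate viability fractions of two monotherapy arms and one
#' combination arm: the best monotherapy is the arm with the lower mean
#' viability; `delta_via` is mean(best mono) - mean(combination) (viability
#' saved by combining), `hr` is mean(combination) / mean(best mono), and the
#' score is `delta_via - delta_via * hr`. With these mean-based estimators
#' the score equals `delta_via^2 / mean(best mono)` and is therefore
#' non-negative, zero exactly when the combination performs no better than
#' the best single agent. A combination is called synergistic when the score
#' exceeds `cutoff` (default 0.004).
#'
#' Replicates are unpaired across arms; only arm means enter the score.
#' Viabilities above 1 (wells outgrowing the control) are retained.
#'
#' @param mono_a,mono_b Replicate viability fractions of the two
#'   monotherapy arms.
#' @param combo Replicate viability fractions of the combination arm.
#' @param cutoff Synergy decision bound.
#' @return An `idacombo_score` object: list with `score`, `delta_via`,
#'   `hr`, `best_mono` (1 or 2), `means`, `cutoff`, `synergy`.
#' @export
idacombo_score <- function(mono_a, mono_b, combo, cutoff = 0.004) {
  arms <- list(mono_a = mono_a, mono_b = mono_b, combo = combo)
  if (any(!lengths(arms))) stop("every arm needs at least one replicate")
  if (any(vapply(arms, function(a) any(!is.finite(a)) || any(a < 0), NA)))
    stop("viabilities must be finite and non-negative")
  means <- vapply(arms, mean, 0)
  best <- which.min(means[1:2])
  delta_via <- means[[best]] - means[["combo"]]
  hr <- means[["combo"]] / means[[best]]
  score <- delta_via - delta_via * hr
  structure(list(score = score, delta_via = delta_via, hr = hr,
                 best_mono = unname(best), means = means, cutoff = cutoff,
                 synergy = score > cutoff),
            class = "idacombo_score")
}

#' @export
print.idacombo_score <- function(x, ...) {
  cat(sprintf(
    "Combination score: %.4f (delta_via %.4f, HR %.4f, best mono arm %d)\n",
    x$score, x$delta_via, x$hr, x$best_mono))
  cat(sprintf("  %s at cutoff %.3f\n",
              if (x$synergy) "SYNERGISTIC" else "not synergistic", x$cutoff))
  invisible(x)
}

#' Replicate viabilities from the T-47D bleomycin + bortezomib experiment
#'
#' Eight-replicate CCK-8 viability fractions of T-47D breast-cancer cells
#' treated at the optimal single-agent concentrations (bleomycin 200 nmol/L,
#' bortezomib 40 nmol/L) and with their combination administered in both
#' orders (arms `Combination1` and `Combination2`).
#'
#' @return Named list of numeric replicate vectors, one per arm.
#' @export
t47d_viability <- function() {
  read_viability_table(system.file("extdata", "t47d_viability.csv",
                                   package = "pathsyn", mustWork = TRUE))
}
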