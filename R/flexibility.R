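# Rigid/flexible classification from implicit-solvent energy traces.
#
# A trace carries, per saved MD frame, the instantaneous solvation energy
# (aqueous minus vacuum potential energy of the same conformation). A
# molecule is called rigid when the SD of this quantity over the trajectory
# is small (<= 0.4 kcal/mol) AND the first-frame ("static") estimate is close
# (within 0.2 kcal/mol) to the whole-trajectory estimate, which weeds out
# molecules whose deposited conformer is unrepresentative. The trajectory
# estimate is the Bennett acceptance ratio when the two-ensemble
# cross-energies are available, else the mean of the per-frame values.

kB_KCAL <- 0.0019872041 # Boltzmann constant, kcal/mol/K

#' Construct an energy trace
#'
#' @param id molecule id.
#' @param dg_frames per-frame instantaneous solvation energy, kcal/mol
#'   (aqueous minus vacuum potential energy of the same conformation);
#'   length >= 2.
#' @param u_cross optional cross-evaluated potential energies for BAR: a list
#'   with numeric vectors `forward` (`U_target - U_reference` on
#'   reference-ensemble frames) and `reverse` (`U_reference - U_target` on
#'   target-ensemble frames), kcal/mol.
#' @param temperature K (default 298.15).
#' @return an object of class `energy_trace`.
#' @export
energy_trace <- function(id, dg_frames, u_cross = NULL, temperature = 298.15) {
  dg_frames <- as.numeric(dg_frames)
  if (length(dg_frames) < 2L) stop("trace ", id, ": need at least 2 frames")
  if (any(!is.finite(dg_frames))) stop("trace ", id, ": non-finite frame energy")
  if (temperature <= 0) stop("temperature must be positive")
  if (!is.null(u_cross)) {
    if (!all(c("forward", "reverse") %in% names(u_cross))) {
      stop("u_cross must have components 'forward' and 'reverse'")
    }
    if (length(u_cross$forward) == 0L || length(u_cross$reverse) == 0L) {
      stop("u_cross components must be non-empty")
    }
  }
  structure(list(id = as.character(id), dg_frames = dg_frames,
                 u_cross = u_cross, temperature = temperature),
            class = "energy_trace")
}

#' First-frame value and frame-to-frame spread of a trace
#'
#' @param trace an [energy_trace()].
#' @return list with `dg_static` (first frame's solvation energy) and `sigma`
#'   (sample SD over frames, n-1 denominator), both kcal/mol.
#' @export
trace_summary <- function(trace) {
  stopifnot(inherits(trace, "energy_trace"))
  list(dg_static = trace$dg_frames[1L], sigma = stats::sd(trace$dg_frames))
}

#' Bennett acceptance ratio free energy between two states
#'
#' Solves the self-consistent Bennett equation
#' `sum_f f(beta*(dU_f - C)) = sum_r f(beta*(dU_r + C))`, with `f` the Fermi
#' function `1/(1+exp(x))` and `C = dG + kT*log(n_f/n_r)`, by bracketed root
#' finding to 1e-10 kcal/mol.
#'
#' @param dU_forward `U_target - U_reference` evaluated on reference-ensemble
#'   samples, kcal/mol.
#' @param dU_reverse `U_reference - U_target` evaluated on target-ensemble
#'   samples, kcal/mol.
#' @param temperature K.
#' @return free energy difference target minus reference, kcal/mol.
#' @export
bar_free_energy <- function(dU_forward, dU_reverse, temperature = 298.15) {
  if (length(dU_forward) == 0L || length(dU_reverse) == 0L) {
    stop("both sample sets must be non-empty")
  }
  if (any(!is.finite(dU_forward)) || any(!is.finite(dU_reverse))) {
    stop("energy differences must be finite")
  }
  beta <- 1 / (kB_KCAL * temperature)
  fermi <- function(x) 1 / (1 + exp(x))
  # monotone increasing in C: LHS grows, RHS shrinks
  g <- function(C) {
    sum(fermi(beta * (dU_forward - C))) - sum(fermi(beta * (dU_reverse + C)))
  }
  lo <- -1; hi <- 1
  while (g(lo) > 0 && lo > -1e6) lo <- lo * 2
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (g(lo) > 0 || g(hi) < 0) {
    stop("Bennett equation has no root within +/- 1e6 kcal/mol: ",
         "insufficient phase-space overlap between the two ensembles")
  }
  C <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  C - log(length(dU_forward) / length(dU_reverse)) / beta
}

#' Exponential-averaging (Zwanzig) free energy
#'
#' One-sided free energy perturbation estimate
#' `-kT * log(mean(exp(-beta*dU)))`, computed with a max-shift so large
#' energy gaps cannot overflow.
#'
#' @param dU per-frame energy differences `U_target - U_reference`, kcal/mol.
#' @param temperature K.
#' @return free energy difference, kcal/mol.
#' @export
exp_avg_free_energy <- function(dU, temperature = 298.15) {
  if (length(dU) == 0L) stop("dU must be non-empty")
  if (any(!is.finite(dU))) stop("energy differences must be finite")
  beta <- 1 / (kB_KCAL * temperature)
  m <- min(dU)
  m - log(mean(exp(-beta * (dU - m)))) / beta
}

#' Rigid/flexible threshold rule
#'
#' A molecule is rigid iff `sigma <= sigma_max` AND
#' `|dg_static - dg_md| <= diff_max`; both boundaries are inclusive. The
#' defaults (0.4 and 0.2 kcal/mol) are the screening thresholds for GB
#' solvation-energy traces.
#'
#' @param dg_static first-frame solvation energy, kcal/mol.
#' @param dg_md whole-trajectory solvation free energy estimate, kcal/mol.
#' @param sigma SD of the per-frame solvation energy, kcal/mol.
#' @param sigma_max,diff_max classification thresholds, kcal/mol.
#' @return `"rigid"` or `"flexible"`.
#' @export
classify_flexibility <- function(dg_static, dg_md, sigma,
                                 sigma_max = 0.4, diff_max = 0.2) {
  stopifnot(is.finite(dg_static), is.finite(dg_md), is.finite(sigma),
            sigma_max > 0, diff_max > 0)
  if (sigma <= sigma_max && abs(dg_static - dg_md) <= diff_max) {
    "rigid"
  } else {
    "flexible"
  }
}

#' Classify a set of energy traces
#'
#' Computes the static estimate, trajectory estimate and frame SD for each
#' trace and applies [classify_flexibility()]. The trajectory estimate uses
#' [bar_free_energy()] when a trace carries cross-energies, else the mean of
#' the per-frame solvation energies; the choice is recorded per molecule.
#'
#' @param traces list of [energy_trace()]s.
#' @param sigma_max,diff_max thresholds, kcal/mol.
#' @return data frame with columns `id`, `dg_static`, `dg_md`, `sigma`,
#'   `label`, `md_estimator`.
#' @export
classify_traces <- function(traces, sigma_max = 0.4, diff_max = 0.2) {
  if (inherits(traces, "energy_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "energy_trace"))
    s <- trace_summary(tr)
    if (!is.null(tr$u_cross)) {
      dg_md <- bar_free_energy(tr$u_cross$forward, tr$u_cross$reverse,
                               tr$temperature)
      est <- "bar"
    } else {
      dg_md <- mean(tr$dg_frames)
      est <- "frame_mean"
    }
    data.frame(id = tr$id, dg_static = s$dg_static, dg_md = dg_md,
               sigma = s$sigma,
               label = classify_flexibility(s$dg_static, dg_md, s$sigma,
                                            sigma_max, diff_max),
               md_estimator = est, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an energy trace from columnar text
#'
#' Expects whitespace- or comma-separated columns `frame`, `u_aq`, `u_vac`
#' (header optional); the per-frame solvation energy is `u_aq - u_vac`. A
#' companion file with the same layout may supply the second (vacuum)
#' ensemble's cross-energies for BAR: its rows are frames sampled in vacuum,
#' evaluated under both Hamiltonians.
#'
#' @param path trace file for the solvated ensemble.
#' @param cross_path optional companion file for the vacuum ensemble.
#' @param id molecule id; defaults to the file name stem.
#' @param temperature K.
#' @return an [energy_trace()].
#' @export
read_energy_trace <- function(path, cross_path = NULL, id = NULL,
                              temperature = 298.15) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  tab <- read_trace_file(path)
  dg <- tab$u_aq - tab$u_vac
  u_cross <- NULL
  if (!is.null(cross_path)) {
    if (!file.exists(cross_path)) stop("no such file: ", cross_path)
    vac <- read_trace_file(cross_path)
    # forward: solvated-minus-vacuum energy on solvated-ensemble frames;
    # reverse: vacuum-minus-solvated energy on vacuum-ensemble frames
    u_cross <- list(forward = tab$u_aq - tab$u_vac,
                    reverse = vac$u_vac - vac$u_aq)
  }
  energy_trace(id, dg, u_cross = u_cross, temperature = temperature)
}

read_trace_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) {
    stop("trace file ", path, " needs columns: frame, u_aq, u_vac")
  }
  if (!header) names(tab)[1:3] <- c("frame", "u_aq", "u_vac")
  if (!all(c("u_aq", "u_vac") %in% names(tab))) {
    stop("trace file ", path, " must name columns u_aq and u_vac")
  }
  if (!is.numeric(tab$u_aq) || !is.numeric(tab$u_vac)) {
    stop("non-numeric energies in trace file ", path)
  }
  tab
}
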