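# Synthetic molecule sets and energy traces with known ground truth. The
# generator emulates the statistical structure the correction models assume:
# element compositions drawn from a palette weighted like a typical
# small-molecule hydration benchmark (H and C common; O and N moderate;
# F, Cl, Br, S uncommon; I and P rare), PMVs roughly additive in atom counts,
# and computed HFEs equal to experiment minus a known linear correction plus
# Gaussian noise. It makes no attempt to simulate solvation physics.

default_palette <- c(H = 0.38, C = 0.34, N = 0.07, O = 0.12, F = 0.02,
                     P = 0.005, S = 0.02, Cl = 0.03, Br = 0.01, I = 0.005)

# Per-element occupied volumes (A^3), Bondi-sphere magnitudes; configuration,
# not science - they only make the synthetic PMVs plausible.
default_volumes <- c(H = 7, C = 20, N = 16, O = 14, F = 13,
                     P = 27, S = 25, Cl = 23, Br = 27, I = 33)

# Ground-truth correction used by default: the benchmark PMVECC coefficients
# (a in kcal/mol/A^3, the rest kcal/mol).
default_true_model <- function() {
  correction_model("PMVECC", a = -0.130, b = 0.00,
                   c = c(H = -0.225, C = -0.148, N = -0.392, O = 0.069,
                         F = -0.05, P = 2.04, S = 0.09, Cl = -1.19,
                         Br = -1.06, I = -0.79))
}

#' Simulate a molecule set from a known correction model
#'
#' Draws element compositions, builds PMVs additively from per-element
#' volumes plus Gaussian noise, samples experimental HFEs uniformly, and sets
#' the "computed" HFE so that the true model's correction recovers experiment
#' up to Gaussian noise:
#' `dg_method = dg_exp - correction_term(true_model, record) + N(0, hfe_noise_sd)`.
#' Resamples (bounded retries) until every palette element occurs in at least
#' two molecules, so leave-one-out folds keep full rank.
#'
#' @param n_molecules number of molecules (default 642, a full benchmark-set
#'   size).
#' @param true_model generating [correction_model()]; default: benchmark
#'   PMVECC coefficients.
#' @param element_palette named sampling weights per element.
#' @param atoms_per_molecule inclusive integer range of atoms per molecule.
#' @param per_element_volume named volumes (A^3) for PMV construction.
#' @param pmv_noise_sd Gaussian noise on PMV, A^3.
#' @param dg_exp_range uniform range of experimental HFEs, kcal/mol.
#' @param hfe_noise_sd Gaussian noise on the computed HFE, kcal/mol
#'   (default 0.5).
#' @param seed integer seed; the same seed reproduces the set bit-for-bit.
#' @return list with `records` (a [molecule_table()]) and `true_model`.
#' @export
simulate_molecules <- function(n_molecules = 642L,
                               true_model = default_true_model(),
                               element_palette = default_palette,
                               atoms_per_molecule = c(5L, 30L),
                               per_element_volume = default_volumes,
                               pmv_noise_sd = 5,
                               dg_exp_range = c(-25, 5),
                               hfe_noise_sd = 0.5,
                               seed = 1L) {
  stopifnot(n_molecules >= 2L, pmv_noise_sd >= 0, hfe_noise_sd >= 0,
            length(atoms_per_molecule) == 2L,
            atoms_per_molecule[1] >= 1L,
            atoms_per_molecule[2] >= atoms_per_molecule[1])
  element_palette <- element_palette[element_palette > 0]
  if (length(element_palette) < 2L) {
    stop("element_palette needs at least two positive weights")
  }
  names(element_palette) <- normalize_element(names(element_palette))
  elements <- element_order_canonical(names(element_palette))
  element_palette <- element_palette[elements]
  missing_vol <- setdiff(elements, names(per_element_volume))
  if (length(missing_vol) > 0L) {
    stop("no per_element_volume for: ", paste(missing_vol, collapse = ", "))
  }
  with_seed(seed, {
    counts <- NULL
    for (try in seq_len(50L)) {
      n_atoms <- sample(seq(atoms_per_molecule[1], atoms_per_molecule[2]),
                        n_molecules, replace = TRUE)
      m <- t(vapply(n_atoms, function(k) {
        tab <- table(factor(sample(elements, k, replace = TRUE,
                                   prob = element_palette),
                            levels = elements))
        as.integer(tab)
      }, integer(length(elements))))
      colnames(m) <- elements
      if (all(colSums(m > 0) >= 2L)) { counts <- m; break }
    }
    if (is.null(counts)) {
      stop("could not draw a set in which every palette element occurs in ",
           ">= 2 molecules after 50 attempts; increase n_molecules or weights")
    }
    pmv <- as.numeric(counts %*% per_element_volume[elements]) +
      stats::rnorm(n_molecules, 0, pmv_noise_sd)
    dg_exp <- stats::runif(n_molecules, dg_exp_range[1], dg_exp_range[2])
    records <- molecule_table(
      id = sprintf("synth_%04d", seq_len(n_molecules)),
      counts = counts, pmv = pmv, dg_exp = dg_exp, dg_exp_unc = 0.1,
      dg_method = 0)
    terms <- vapply(seq_len(n_molecules), function(i) {
      correction_term(true_model,
                      list(id = records$id[i], pmv = pmv[i],
                           counts = counts[i, ]),
                      permissive = FALSE)
    }, numeric(1))
    records$dg_method <- dg_exp - terms +
      stats::rnorm(n_molecules, 0, hfe_noise_sd)
    list(records = records, true_model = true_model)
  })
}

#' Simulate Gaussian energy traces with known flexibility labels
#'
#' Each trace draws a frame-to-frame spread `sigma` and a first-frame offset
#' uniformly from the given ranges, then emits Gaussian per-frame solvation
#' energies around a random baseline; frame 1 is displaced to
#' `baseline + offset`. The true label applies the threshold rule to the
#' generating population values (`sigma` and `|offset|`), which [classify_traces()]
#' should reproduce from the sampled frames when the draws are away from the
#' thresholds.
#'
#' @param n_traces number of traces.
#' @param frames frames per trace (>= 10).
#' @param sigma_range uniform range of the frame SD, kcal/mol.
#' @param offset_range uniform range of the first-frame offset, kcal/mol.
#' @param sigma_max,diff_max thresholds used for the true labels, kcal/mol.
#' @param seed integer seed.
#' @return list with `traces` (list of [energy_trace()]) and `truth` (data
#'   frame `id`, `sigma_true`, `offset_true`, `label_true`).
#' @export
simulate_traces <- function(n_traces, frames = 10000L,
                            sigma_range = c(0.05, 1.5),
                            offset_range = c(-0.6, 0.6),
                            sigma_max = 0.4, diff_max = 0.2,
                            seed = 1L) {
  stopifnot(frames >= 10L, n_traces >= 1L)
  with_seed(seed, {
    sigma <- stats::runif(n_traces, sigma_range[1], sigma_range[2])
    offset <- stats::runif(n_traces, offset_range[1], offset_range[2])
    baseline <- stats::runif(n_traces, -15, 0)
    ids <- sprintf("trace_%04d", seq_len(n_traces))
    traces <- lapply(seq_len(n_traces), function(i) {
      frames_i <- stats::rnorm(frames, baseline[i], sigma[i])
      frames_i[1L] <- baseline[i] + offset[i]
      energy_trace(ids[i], frames_i)
    })
    truth <- data.frame(
      id = ids, sigma_true = sigma, offset_true = offset,
      label_true = ifelse(sigma <= sigma_max & abs(offset) <= diff_max,
                          "rigid", "flexible"),
      stringsAsFactors = FALSE)
    list(traces = traces, truth = truth)
  })
}
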