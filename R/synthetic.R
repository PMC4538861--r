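# Synthetic dose-response data -------------------------------------------
#
# Stand-in for the densitometry/ELISA measurements: Hill-shaped ground
# truths sampled on a log dose grid with multiplicative lognormal
# replicate noise, normalized per replicate to the observed maximum
# (the pY/pY_MAX presentation, which slightly biases sub-maximal points
# downward and which fitting must tolerate).  The generating truth
# travels with the dataset so recovery can be tested.

#' Generator configuration
#'
#' @param doses log-spaced EGF grid (ng/ml), strictly increasing.
#' @param truths named list of truth curves; each a list with
#'   \code{kind} ("pY"/"Ub"), \code{mutant}, \code{n_h}, \code{x_half}
#'   (ng/ml) and \code{plateau} (arbitrary units).
#' @param replicates independent replicate experiments per condition.
#' @param cv coefficient of variation of the multiplicative lognormal
#'   noise (0.10 mimics densitometry error bars over >= 3 experiments).
#' @param seed RNG seed.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(doses = default_dose_grid(),
                             truths = default_truths(),
                             replicates = 3L, cv = 0.10, seed = 1L) {
  stopifnot(!is.unsorted(doses, strictly = TRUE), cv >= 0, replicates >= 1)
  structure(list(doses = doses, truths = truths,
                 replicates = as.integer(replicates), cv = cv,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default ground-truth curves
#'
#' Phosphorylation is hyperbolic (n_H = 1); ubiquitination of the
#' WT-like 3Y+ receptor is switch-like (n_H = 3) with its threshold
#' inside the 1-10 ng/ml window; the Y1045+ single-site receptor loses
#' both the threshold and ~80% of maximal ubiquitination; Cbl
#' overexpression / 70Z double / halve the absolute signal without
#' moving the threshold.
#'
#' @export
default_truths <- function() {
  list(
    py_3yplus = list(kind = "pY", mutant = "3yplus", n_h = 1,
                     x_half = 2, plateau = 1),
    ub_3yplus = list(kind = "Ub", mutant = "3yplus", n_h = 3,
                     x_half = 3, plateau = 1),
    ub_y1045plus = list(kind = "Ub", mutant = "y1045plus", n_h = 1,
                        x_half = 2, plateau = 0.2),
    ub_cbl_oe = list(kind = "Ub", mutant = "3yplus", n_h = 3,
                     x_half = 3, plateau = 2),
    ub_cbl_70z = list(kind = "Ub", mutant = "3yplus", n_h = 3,
                      x_half = 3, plateau = 0.5))
}

.hill_eval <- function(x, n_h, x_half, plateau) {
  plateau * x^n_h / (x_half^n_h + x^n_h)
}

#' Generate a synthetic replicate dose-response dataset
#'
#' Measurements are truth(dose) times lognormal noise with the
#' configured CV; each replicate curve is then normalized to its own
#' observed maximum, after the noise, as densitometry is.
#'
#' @param config a [generator_config()].
#' @return data.frame of class \code{synthetic_dataset} with columns
#'   \code{condition}, \code{mutant}, \code{egf_ng_per_ml},
#'   \code{replicate}, \code{readout_kind}, \code{value},
#'   \code{value_normalized}; the generating truth is attached as
#'   attribute \code{truth}.
#' @export
generate_dose_response <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sdlog <- if (config$cv > 0) sqrt(log(1 + config$cv^2)) else 0
  rows <- list()
  for (cond in names(config$truths)) {
    tr <- config$truths[[cond]]
    mu <- .hill_eval(config$doses, tr$n_h, tr$x_half, tr$plateau)
    for (rep in seq_len(config$replicates)) {
      noise <- if (sdlog > 0) {
        stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, length(mu))
      v <- mu * noise
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, mutant = tr$mutant,
        egf_ng_per_ml = config$doses, replicate = rep,
        readout_kind = tr$kind, value = v,
        value_normalized = if (max(v) > 0) v / max(v) else v,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- config$truths
  attr(out, "config") <- config
  class(out) <- c("synthetic_dataset", "data.frame")
  out
}

#' Replicate-averaged normalized curve for one condition
#'
#' @param dataset a [generate_dose_response()] result.
#' @param condition condition name.
#' @param normalized average the per-replicate normalized values
#'   (default) or the absolute ones.
#' @return a [dose_response()].
#' @export
dataset_curve <- function(dataset, condition, normalized = TRUE) {
  d <- dataset[dataset$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("unknown condition: ", condition)
  col <- if (normalized) "value_normalized" else "value"
  agg <- stats::aggregate(d[[col]], by = list(egf = d$egf_ng_per_ml), mean)
  agg <- agg[order(agg$egf), ]
  dose_response(agg$egf, agg$x,
                kind = if (d$readout_kind[1L] == "pY") "pY" else "Ub")
}

#' Measured molecule-count profiles
#'
#' Copy numbers per cell from saturation binding (EGFR) and
#' quantitative immunoblotting (Grb2, Cbl, active Cbl-pY): HeLa plus
#' the EGFR-knockdown HeLa (4.2-fold receptor loss) and the three NIH
#' 3T3 EGFR clones.
#'
#' @param name profile name.
#' @return list of class \code{cell_profile} with \code{egfr},
#'   \code{grb2}, \code{cbl_total}, \code{cbl_available}.
#' @export
cell_profile <- function(name = c("hela", "hela_egfr_kd", "nih_phy",
                                  "nih_mov", "nih_hov")) {
  name <- match.arg(name)
  hela <- list(egfr = 3e5, grb2 = 1e6, cbl_total = 1.5e5,
               cbl_available = 5e3)
  p <- switch(name,
    hela = hela,
    hela_egfr_kd = utils::modifyList(hela, list(egfr = 3e5 / 4.2)),
    nih_phy = utils::modifyList(hela, list(egfr = 7e4)),
    nih_mov = utils::modifyList(hela, list(egfr = 2e5)),
    nih_hov = utils::modifyList(hela, list(egfr = 6e5)))
  structure(c(p, list(name = name)), class = "cell_profile")
}

#' Receptor mutant site configurations
#'
#' @param name "wt" (nine phosphorylatable tyrosines, three of them
#'   adaptor-competent), "3yplus" (Y1045/Y1068/Y1086 only), "y1045plus"
#'   (direct Cbl site only) or "y106886plus" (Grb2 sites only).
#' @return list with \code{n_sites}, \code{cbl_site} (logical),
#'   \code{grb2_sites} (character vector of Grb2-competent sites).
#' @export
mutant_config <- function(name = c("wt", "3yplus", "y1045plus",
                                   "y106886plus")) {
  name <- match.arg(name)
  switch(name,
    wt = list(name = name, n_sites = 9L, cbl_site = TRUE,
              grb2_sites = c("Y1068", "Y1086")),
    "3yplus" = list(name = name, n_sites = 3L, cbl_site = TRUE,
                    grb2_sites = c("Y1068", "Y1086")),
    y1045plus = list(name = name, n_sites = 1L, cbl_site = TRUE,
                     grb2_sites = character(0)),
    y106886plus = list(name = name, n_sites = 2L, cbl_site = FALSE,
                       grb2_sites = c("Y1068", "Y1086")))
}

#' Apply a molecule-count profile to a parameter set
#'
#' @param params [mpmb_params()] or [eam_params()].
#' @param profile a [cell_profile()] (or its name).
#' @export
apply_profile <- function(params, profile = "hela") {
  if (is.character(profile)) profile <- cell_profile(profile)
  params$r_total <- profile$egfr
  params$cbl_total <- profile$cbl_available
  params$grb2_total <- profile$grb2
  params
}
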