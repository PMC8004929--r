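#' Design of a destructive-sampling biodistribution study
#'
#' Defaults reproduce the in vivo study design: 0.1 mg/kg IV bolus into
#' 28 g mice, terminal sampling at 5 min and 1, 6, 12, 24 and 168 h, three
#' animals per time point, with plasma, whole blood, 11 tissues and tumor
#' collected from every animal, an assay LLOQ of 0.2 ng/mL, and residual
#' error following the combined additive-proportional variance model
#' `V = (sigma1 + sigma2 * Y)^2` (sigma1 in nM, sigma2 a fraction).
#'
#' @param dose_per_bw dose, mg/kg.
#' @param body_weight body weight, g.
#' @param sample_times terminal sampling times, h (positive, sorted).
#' @param animals_per_time animals sacrificed per time point.
#' @param matrices matrices measured on each animal.
#' @param LLOQ lower limit of quantification, ng/mL.
#' @param sigma1 additive error SD, nM.
#' @param sigma2 proportional error fraction.
#' @param seed RNG seed for replicate noise.
#' @return object of class `study_design`.
#' @export
study_design <- function(dose_per_bw = 0.1, body_weight = 28,
                         sample_times = c(5 / 60, 1, 6, 12, 24, 168),
                         animals_per_time = 3, matrices = .matrices,
                         LLOQ = 0.2, sigma1 = 0.01, sigma2 = 0.10,
                         seed = 1) {
  if (any(sample_times <= 0) || is.unsorted(sample_times, strictly = TRUE))
    stop("sample_times must be positive and strictly increasing",
         call. = FALSE)
  if (animals_per_time < 1)
    stop("animals_per_time must be >= 1", call. = FALSE)
  if (LLOQ < 0) stop("LLOQ must be >= 0", call. = FALSE)
  if (sigma1 < 0 || sigma2 < 0)
    stop("variance parameters must be >= 0", call. = FALSE)
  matrices <- .canon_matrix(matrices)
  structure(list(dose_per_bw = dose_per_bw, body_weight = body_weight,
                 sample_times = sample_times,
                 animals_per_time = as.integer(animals_per_time),
                 matrices = matrices, LLOQ = LLOQ,
                 sigma1 = sigma1, sigma2 = sigma2, seed = as.integer(seed)),
            class = "study_design")
}

# deterministic zero-truncated normal draw via inverse CDF
.rtruncnorm0 <- function(n, mean, sd) {
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), lo, 1)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmax(out, 0)
}

#' Generate a synthetic biodistribution study
#'
#' Simulates the PBPK model under the study design, evaluates the
#' homogenate-equivalent observables at the sampling times, and draws each
#' replicate from the residual-error model: Normal with mean `Y` and SD
#' `sigma1 + sigma2 * Y`, truncated at zero (`noise = "truncnorm"`, the
#' default, mirroring the additive-proportional variance literally) or
#' log-normal with matched CV (`noise = "lognormal"`). Records below the
#' LLOQ keep their value and are flagged BLQ. Each animal (replicate index)
#' contributes all matrices at its terminal time. Fully reproducible from
#' the design seed.
#'
#' @param design a [study_design()].
#' @param phys,drug,tum model parameter objects.
#' @param noise residual-error form.
#' @param seed optional override of `design$seed`.
#' @return a `study_dataset`: data frame with columns `matrix`, `time_h`,
#'   `replicate`, `conc_nM`, `conc_ng_mL`, `blq`, plus attributes
#'   `true_nM` (noise-free observable per record) and `design`.
#' @export
generate_study <- function(design, phys, drug, tum,
                           noise = c("truncnorm", "lognormal"),
                           seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  noise <- match.arg(noise)
  if (is.null(seed)) seed <- design$seed
  if (max(design$sample_times) > 200)
    stop("design times exceed the 200 h simulation horizon", call. = FALSE)

  sim <- simulate_pbpk(dose_event(design$dose_per_bw, design$body_weight),
                       phys, drug, tum, times = design$sample_times)
  Y <- sim$obs_nM[match(design$sample_times, sim$times), design$matrices,
                  drop = FALSE]

  rec <- expand.grid(replicate = seq_len(design$animals_per_time),
                     matrix = design$matrices,
                     time_h = design$sample_times,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- rec[, c("matrix", "time_h", "replicate")]
  mu <- Y[cbind(match(rec$time_h, design$sample_times),
                match(rec$matrix, design$matrices))]
  sdv <- design$sigma1 + design$sigma2 * mu

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  conc <- if (noise == "truncnorm") {
    .rtruncnorm0(nrow(rec), mu, sdv)
  } else {
    cv <- ifelse(mu > 0, sdv / mu, 0)
    s2 <- log(1 + cv^2)
    ifelse(mu > 0,
           stats::rlnorm(nrow(rec), log(mu) - s2 / 2, sqrt(s2)), 0)
  }

  out <- data.frame(matrix = rec$matrix, time_h = rec$time_h,
                    replicate = rec$replicate, conc_nM = conc,
                    conc_ng_mL = convert_units(conc, "nM_to_ng_per_mL",
                                               drug$MW),
                    blq = FALSE, stringsAsFactors = FALSE)
  out <- censor_dataset(out, design$LLOQ)
  attr(out, "true_nM") <- mu
  attr(out, "design") <- design
  class(out) <- c("study_dataset", "data.frame")
  out
}

#' Flag below-LLOQ records
#'
#' Sets the BLQ flag on records whose ng/mL concentration is below the
#' LLOQ; values are retained. Idempotent.
#'
#' @param dataset a `study_dataset` (or compatible data frame).
#' @param LLOQ lower limit of quantification, ng/mL.
#' @return the dataset with the `blq` column recomputed.
#' @export
censor_dataset <- function(dataset, LLOQ) {
  if (LLOQ < 0) stop("LLOQ must be >= 0", call. = FALSE)
  dataset$blq <- dataset$conc_ng_mL < LLOQ
  dataset
}
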