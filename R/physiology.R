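#' Load a mouse physiology table
#'
#' Reads the per-tissue anatomical/physiological constants consumed by the
#' PBPK model: total volumes, sub-compartment volume fractions (vascular,
#' endothelial, interstitial, cellular) and regional blood flows. Two fixtures
#' ship with the package for a 28 g tumor-bearing mouse:
#' `"mouse_28g"` (default; cellular fractions calibrated so that the ratio of
#' apparent to cellular-space-adjusted partition coefficients is reproduced
#' per tissue) and `"mouse_28g_literature"` (generic cellular fractions).
#' Both are synthetic stand-in tables assembled from standard rodent PBPK
#' physiology; every downstream quantity that depends on them is
#' fixture-sensitive.
#'
#' The vascular space is split into plasma and blood cells with the
#' hematocrit, both for volumes and for regional flows (see [split_flows()]).
#'
#' @param source fixture name (`"mouse_28g"` or `"mouse_28g_literature"`) or
#'   path to a CSV file with columns `tissue, V_total_mL, f_vascular,
#'   f_endothelial, f_interstitial, f_cellular, Q_blood_mL_h`.
#' @param hematocrit volume fraction of blood occupied by blood cells,
#'   in (0, 1).
#' @param body_weight body weight in g (bookkeeping; the dose amount is
#'   computed from the dosed animal's weight, not from this table).
#' @return An object of class `physiology_table`: a list with elements
#'   `table` (the validated data frame, one row per tissue), `hematocrit`
#'   and `body_weight`.
#' @examples
#' phys <- load_physiology()
#' phys$table[phys$table$tissue == "kidney", ]
#' @export
load_physiology <- function(source = "mouse_28g", hematocrit = 0.45,
                            body_weight = 28) {
  if (!is.numeric(hematocrit) || length(hematocrit) != 1 ||
      hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("body_weight must be positive", call. = FALSE)

  path <- if (file.exists(source)) {
    source
  } else {
    system.file("extdata", paste0("physiology_", source, ".csv"),
                package = "mmaepbpk")
  }
  if (!nzchar(path) || !file.exists(path))
    stop("physiology source not found: ", source, call. = FALSE)

  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tissue", "V_total_mL", "f_vascular", "f_endothelial",
            "f_interstitial", "f_cellular", "Q_blood_mL_h")
  if (!all(need %in% names(tab)))
    stop("physiology table is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)

  required <- c("blood", .tissues)
  missing <- setdiff(required, tab$tissue)
  if (length(missing))
    stop("physiology table is missing tissue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- tab[match(required, tab$tissue), , drop = FALSE]
  rownames(tab) <- tab$tissue

  num <- c("V_total_mL", "f_vascular", "f_endothelial", "f_interstitial",
           "f_cellular", "Q_blood_mL_h")
  if (any(!vapply(tab[num], is.numeric, logical(1))) ||
      anyNA(tab[num]))
    stop("physiology table contains non-numeric or missing values",
         call. = FALSE)
  if (any(tab$V_total_mL <= 0) || any(tab$Q_blood_mL_h <= 0))
    stop("all volumes and flows must be strictly positive", call. = FALSE)

  fsum <- tab$f_vascular + tab$f_endothelial + tab$f_interstitial +
    tab$f_cellular
  bad <- which(abs(fsum - 1) > 1e-9)
  if (length(bad))
    stop("sub-compartment fractions do not sum to 1 for ",
         paste(tab$tissue[bad], collapse = ", "),
         " (residual ", paste(signif(fsum[bad] - 1, 3), collapse = ", "), ")",
         call. = FALSE)

  # cardiac output (lung flow) must equal the sum of the regional flows
  regional <- setdiff(.tissues, "lung")
  q_sum <- sum(tab[regional, "Q_blood_mL_h"])
  q_lung <- tab["lung", "Q_blood_mL_h"]
  if (abs(q_sum - q_lung) > 1e-9 * q_lung)
    stop("regional blood flows (", signif(q_sum, 10),
         " mL/h) do not sum to the lung (cardiac-output) flow (",
         signif(q_lung, 10), " mL/h)", call. = FALSE)

  structure(list(table = tab, hematocrit = hematocrit,
                 body_weight = body_weight),
            class = "physiology_table")
}

#' @export
print.physiology_table <- function(x, ...) {
  cat("Mouse physiology table:", nrow(x$table), "tissues,",
      "body weight", x$body_weight, "g, hematocrit", x$hematocrit, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Split a whole-blood flow into plasma and blood-cell flows
#'
#' The model circulates plasma and blood cells as parallel streams; a
#' regional whole-blood flow is split by hematocrit.
#'
#' @param Q_blood whole-blood flow, mL/h.
#' @param hematocrit blood-cell volume fraction, in (0, 1).
#' @return list with `Q_plasma` and `Q_BC` (mL/h); their sum equals
#'   `Q_blood`.
#' @examples
#' split_flows(10, 0.45)
#' @export
split_flows <- function(Q_blood, hematocrit) {
  if (any(Q_blood <= 0)) stop("Q_blood must be positive", call. = FALSE)
  if (any(hematocrit <= 0) || any(hematocrit >= 1))
    stop("hematocrit must be in (0, 1)", call. = FALSE)
  list(Q_plasma = Q_blood * (1 - hematocrit), Q_BC = Q_blood * hematocrit)
}

#' Tumor volume from its radius
#'
#' The tumor is treated as a sphere; the volume enters the plasma-tumor
#' exchange terms of the model.
#'
#' @param R_tumor tumor radius, cm.
#' @return volume in mL (= cm^3).
#' @examples
#' tumor_volume(0.7)
#' @export
tumor_volume <- function(R_tumor) {
  if (any(R_tumor <= 0)) stop("R_tumor must be positive", call. = FALSE)
  4 / 3 * pi * R_tumor^3
}

# Absolute sub-compartment volumes (mL) for one tissue:
# named c(plasma, bc, endo, is, cell)
.sub_volumes <- function(phys, tissue) {
  row <- phys$table[tissue, ]
  hct <- phys$hematocrit
  c(plasma = row$V_total_mL * row$f_vascular * (1 - hct),
    bc     = row$V_total_mL * row$f_vascular * hct,
    endo   = row$V_total_mL * row$f_endothelial,
    is     = row$V_total_mL * row$f_interstitial,
    cell   = row$V_total_mL * row$f_cellular)
}
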