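#' Ellipse cross-section area from measured diameters
#'
#' The tumor is measured on the coronal section where it is largest,
#' assuming an approximately ellipsoidal shape: area = pi a b with
#' semi-axes a = A/2 and b = B/2, where A and B are the major and minor
#' diameters.
#'
#' @param A_diam Major diameter in mm (>= 0).  Vectorized.
#' @param B_diam Minor diameter in mm (>= 0).  Vectorized.
#' @return Cross-section area in mm^2.
#' @examples
#' ellipse_area(6, 4)   # pi * 3 * 2 = 18.85
#' ellipse_area(2, 2)   # unit-radius circle, pi
#' @export
ellipse_area <- function(A_diam, B_diam) {
  if (any(A_diam < 0) || any(B_diam < 0))
    stop("diameters must be >= 0")
  pi * (A_diam / 2) * (B_diam / 2)
}

#' Dose normalized to body mass
#'
#' Converts a daily dose in mg to mg/kg for a given body mass in grams,
#' optionally rounded to the nearest multiple of a step (half-away-from-zero
#' on the step grid).  The rat dosing arithmetic of the study: 10 mg daily
#' for a 150 g animal is 66.7 mg/kg, i.e. approximately 65 mg/kg on a
#' 5 mg/kg grid.
#'
#' @param dose_mg Daily dose in mg (>= 0).
#' @param body_mass_g Body mass in g (> 0).
#' @param round_to Optional step in mg/kg to round to (e.g. 5), or
#'   \code{NULL} (default) for the exact value.
#' @return Dose in mg per kg body mass per day.
#' @examples
#' dose_per_kg(10, 150)               # 66.67
#' dose_per_kg(10, 150, round_to = 5) # 65
#' @export
dose_per_kg <- function(dose_mg, body_mass_g, round_to = NULL) {
  if (any(body_mass_g <= 0)) stop("body mass must be > 0")
  if (any(dose_mg < 0)) stop("dose must be >= 0")
  x <- dose_mg / (body_mass_g / 1000)
  if (!is.null(round_to)) {
    if (round_to <= 0) stop("'round_to' must be > 0")
    # round half away from zero on the step grid (not banker's rounding)
    x <- sign(x) * floor(abs(x) / round_to + 0.5) * round_to
  }
  x
}

#' Read tumor size measurements from CSV
#'
#' Expects columns \code{animal_id}, \code{group}, \code{day} and either the
#' diameters \code{A_mm}, \code{B_mm} (major/minor, in mm) or a direct area
#' column \code{area_mm2}.  When diameters are given the area is computed
#' with \code{\link{ellipse_area}}.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns \code{animal_id}, \code{group},
#'   \code{day}, \code{area_mm2}.
#' @export
read_size_measurements <- function(path) {
  if (!file.exists(path)) stop("size measurement file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("animal_id", "group", "day")
  if (!all(needed %in% names(d)))
    stop("size CSV must contain columns: ", paste(needed, collapse = ", "))
  if ("area_mm2" %in% names(d)) {
    area <- as.numeric(d$area_mm2)
  } else if (all(c("A_mm", "B_mm") %in% names(d))) {
    if (any(d$A_mm < d$B_mm, na.rm = TRUE))
      stop("major diameter A_mm must be >= minor diameter B_mm")
    area <- ellipse_area(d$A_mm, d$B_mm)
  } else {
    stop("size CSV must contain either 'area_mm2' or both 'A_mm' and 'B_mm'")
  }
  if (any(!is.finite(area)) || any(area < 0))
    stop("tumor areas must be finite and >= 0")
  data.frame(animal_id = as.character(d$animal_id),
             group = as.character(d$group),
             day = as.integer(d$day),
             area_mm2 = area,
             stringsAsFactors = FALSE)
}
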