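#' Pairwise judgment matrix
#'
#' Validates an AHP pairwise-comparison matrix: square, positive, unit
#' diagonal and reciprocal (`a_ji = 1 / a_ij`).
#'
#' @param m Numeric square matrix.
#' @return The matrix with class `judgment_matrix`.
#' @export
judgment_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("judgment matrix must be square.")
  if (any(m <= 0)) abort("judgment matrix entries must be positive.")
  if (any(abs(diag(m) - 1) > 1e-9)) abort("diagonal entries must equal 1.")
  if (any(abs(m * t(m) - 1) > 1e-6)) {
    abort("matrix is not reciprocal: a_ji must equal 1/a_ij.")
  }
  structure(m, class = c("judgment_matrix", "matrix"))
}

# Random consistency indices (Saaty), n = 1..10.
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP weights from a judgment matrix
#'
#' Geometric-mean (logarithmic least squares) prioritization: the weight of
#' row `i` is the geometric mean of its comparisons, normalized to sum
#' to 1. The consistency ratio `CR = CI / RI` is reported, with
#' `CI = (lambda_max - n)/(n - 1)` and Saaty's random index `RI`; a warning
#' is raised when `CR > 0.1`.
#'
#' @param m A [judgment_matrix()] (or coercible matrix).
#' @return A tibble of class `ahp_weights` with columns `item`, `weight`;
#'   `lambda_max`, `ci` and `cr` are attached as attributes and reported by
#'   [glance()].
#' @examples
#' ahp_weights(matrix(1, 3, 3))
#' @export
ahp_weights <- function(m) {
  m <- judgment_matrix(unclass(m))
  n <- nrow(m)
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  w <- gm / sum(gm)
  lambda_max <- mean((m %*% w) / w)
  ci <- if (n > 2) (lambda_max - n) / (n - 1) else 0
  ri <- if (n <= length(saaty_ri)) saaty_ri[n] else 1.49
  cr <- if (n > 2 && ri > 0) ci / ri else 0
  if (cr > 0.1) {
    warn(sprintf("judgment matrix inconsistent: CR = %.3f > 0.1", cr))
  }
  items <- rownames(m) %||% paste0("item", seq_len(n))
  out <- tibble::tibble(item = items, weight = w)
  structure(out, lambda_max = lambda_max, ci = ci, cr = cr,
            class = c("ahp_weights", class(out)))
}

#' @export
glance.ahp_weights <- function(x, ...) {
  tibble::tibble(n = nrow(x), lambda_max = attr(x, "lambda_max"),
                 ci = attr(x, "ci"), cr = attr(x, "cr"))
}

#' Laser-interference grading hierarchy
#'
#' The four-criterion hierarchy used to grade laser visual interference:
#' incident laser radiation characteristics (`U-A`, indicators A1--A5),
#' retinal physiological damage (`U-B`, B1--B2), retinal imaging
#' characteristics (`U-C`, C1--C3) and laser glare perception (`U-D`,
#' D1--D5), each indicator carrying the printed number of leaf factors
#' (A: 3,3,2,2,3; B: 3,2; C: 3,2,2; D: 2,2,2,2,1).
#'
#' Judgment matrices for any internal node can be supplied through
#' `matrices`, a named list keyed by node name (`"root"`, `"U-A"`, `"A1"`,
#' ...); nodes without a matrix get an all-ones matrix (equal weights).
#'
#' @param matrices Named list of judgment matrices (optional).
#' @return An object of class `grading_hierarchy`.
#' @export
grading_hierarchy <- function(matrices = list()) {
  shape <- list(
    "U-A" = c(A1 = 3, A2 = 3, A3 = 2, A4 = 2, A5 = 3),
    "U-B" = c(B1 = 3, B2 = 2),
    "U-C" = c(C1 = 3, C2 = 2, C3 = 2),
    "U-D" = c(D1 = 2, D2 = 2, D3 = 2, D4 = 2, D5 = 1))
  leaves <- purrr::imap(shape, function(ind, crit) {
    purrr::imap(as.list(ind), function(k, nm) paste0(nm, seq_len(k)))
  })
  structure(list(shape = shape, leaves = leaves, matrices = matrices),
            class = "grading_hierarchy")
}

#' Leaf names of a grading hierarchy
#'
#' @param hierarchy A [grading_hierarchy()].
#' @return Character vector of all leaf factor names (A11, A12, ..., D51).
#' @export
hierarchy_leaves <- function(hierarchy) {
  unlist(hierarchy$leaves, use.names = FALSE)
}

node_weights <- function(hierarchy, node, n) {
  m <- hierarchy$matrices[[node]]
  if (is.null(m)) m <- matrix(1, n, n)
  ahp_weights(m)$weight
}

#' Bottom-up criterion score aggregation
#'
#' Composes leaf factor scores into the four criterion scores: each
#' indicator score is the AHP-weighted mean of its factor scores, and each
#' criterion score the weighted mean of its indicator scores. With the
#' default all-ones matrices every mean is unweighted. Scores stay inside
#' the convex hull of the leaf scores.
#'
#' @param leaf_scores Named numeric vector (or one-row data frame) of leaf
#'   factor scores, named as in [hierarchy_leaves()].
#' @param hierarchy A [grading_hierarchy()].
#' @return A tibble with `criterion` (`U-A` ... `U-D`) and `score`.
#' @export
aggregate_scores <- function(leaf_scores, hierarchy = grading_hierarchy()) {
  if (is.data.frame(leaf_scores)) leaf_scores <- unlist(leaf_scores[1, ])
  missing <- setdiff(hierarchy_leaves(hierarchy), names(leaf_scores))
  if (length(missing)) {
    abort(paste0("missing leaf score(s): ", paste(missing, collapse = ", ")))
  }
  crit_scores <- purrr::imap_dbl(hierarchy$shape, function(ind, crit) {
    ind_scores <- purrr::imap_dbl(as.list(ind), function(k, nm) {
      leaves <- paste0(nm, seq_len(k))
      w <- node_weights(hierarchy, nm, k)
      sum(w * leaf_scores[leaves])
    })
    w <- node_weights(hierarchy, crit, length(ind))
    sum(w * ind_scores)
  })
  tibble::tibble(criterion = names(hierarchy$shape),
                 score = unname(crit_scores))
}

#' Grey class intervals for the four criteria
#'
#' The per-criterion score intervals defining the four grey classes (Low,
#' Moderate, High, Extremely High) and their mapping to interference Levels
#' I--IV with qualitative descriptions and laser-safety class labels.
#'
#' @return A list of class `grey_class_spec` with `intervals` (named list
#'   of 5-point breakpoints per criterion) and `levels` (tibble mapping
#'   class to Level, description and IEC class).
#' @export
grey_class_spec <- function() {
  structure(list(
    intervals = list(
      "U-A" = c(0, 2, 4, 5, 6),
      "U-B" = c(0, 3, 5, 6, 9),
      "U-C" = c(0, 2, 3, 4, 5),
      "U-D" = c(0, 2, 3, 4, 5)),
    classes = c("Low", "Moderate", "High", "Extremely High"),
    levels = tibble::tibble(
      class = c("Low", "Moderate", "High", "Extremely High"),
      level = c("I", "II", "III", "IV"),
      iec_class = c("Class 1", "Class 1M", "Class 2", "Class 2M"),
      description = c(
        "No discomfort; little visual obscuration.",
        "Piercing; much visual obscuration; self-healing without treatment.",
        "Piercing and dizziness; much visual obscuration; self-healing without treatment.",
        "Strong piercing, dizziness and burning; much or complete obscuration; recoverable after treatment."))),
    class = "grey_class_spec")
}

#' Grey (whitening) class memberships of a criterion score
#'
#' Trapezoidal whitening functions over the criterion's class intervals:
#' full membership on the interval interior, a linear crossfade between
#' adjacent classes over a band of `band_frac` of the narrower interval's
#' width centred on each boundary. Memberships are normalized to sum to 1;
#' a score exactly on an interior boundary splits 50/50 between the two
#' adjacent classes. Scores above the top interval clamp to Extremely High
#' with a warning.
#'
#' @param score Criterion score.
#' @param criterion One of `"U-A"`, `"U-B"`, `"U-C"`, `"U-D"`.
#' @param spec A [grey_class_spec()].
#' @param band_frac Crossfade band width as a fraction of interval width.
#' @return A tibble with `class` and `membership` (4 rows, summing to 1).
#' @export
grey_classify <- function(score, criterion, spec = grey_class_spec(),
                          band_frac = 0.1) {
  br <- spec$intervals[[criterion]]
  if (is.null(br)) abort(paste0("unknown criterion: ", criterion))
  if (score < br[1]) abort("score below the lowest interval.")
  if (score > br[length(br)]) {
    warn("score above the top interval; clamped to Extremely High.")
    score <- br[length(br)]
  }
  k <- length(br) - 1
  mem <- numeric(k)
  for (i in seq_len(k)) {
    lo <- br[i]; hi <- br[i + 1]
    half_lo <- if (i > 1) {
      band_frac * min(hi - lo, br[i] - br[i - 1]) / 2
    } else 0
    half_hi <- if (i < k) {
      band_frac * min(hi - lo, br[i + 2] - br[i + 1]) / 2
    } else 0
    mem[i] <- trapezoid_membership(score, lo, hi, half_lo, half_hi,
                                   first = i == 1, last = i == k)
  }
  mem <- mem / sum(mem)
  tibble::tibble(class = spec$classes, membership = mem)
}

trapezoid_membership <- function(x, lo, hi, half_lo, half_hi, first, last) {
  if (first) {
    rise <- 1
  } else if (half_lo == 0) {
    rise <- as.numeric(x >= lo)
  } else {
    rise <- pmin(pmax((x - (lo - half_lo)) / (2 * half_lo), 0), 1)
  }
  if (last) {
    fall <- 1
  } else if (half_hi == 0) {
    fall <- as.numeric(x < hi)
  } else {
    fall <- pmin(pmax(((hi + half_hi) - x) / (2 * half_hi), 0), 1)
  }
  pmin(rise, fall)
}

#' Overall interference level from criterion memberships
#'
#' Combines the per-criterion grey memberships into an overall class using
#' the criterion weights (equal by default), picks the class with maximal
#' combined membership — ties broken toward the more severe class, the
#' conservative choice for a safety assessment — and maps it to Level I--IV
#' with its description.
#'
#' @param scores Tibble from [aggregate_scores()] (columns `criterion`,
#'   `score`), or a named numeric vector of criterion scores.
#' @param hierarchy A [grading_hierarchy()] (for the criterion weights).
#' @param spec A [grey_class_spec()].
#' @param band_frac Passed to [grey_classify()].
#' @return A one-row tibble: `level`, `class`, `iec_class`, `description`,
#'   the four class memberships (`m_low` ... `m_extreme`) and the criterion
#'   scores (`E_U_A` ... `E_U_D`).
#' @export
assign_level <- function(scores, hierarchy = grading_hierarchy(),
                         spec = grey_class_spec(), band_frac = 0.1) {
  if (!is.data.frame(scores)) {
    scores <- tibble::tibble(criterion = names(scores),
                             score = as.numeric(scores))
  }
  crits <- names(spec$intervals)
  w <- node_weights(hierarchy, "root", length(crits))
  mem_mat <- sapply(seq_along(crits), function(i) {
    grey_classify(scores$score[scores$criterion == crits[i]],
                  crits[i], spec, band_frac)$membership
  })
  combined <- as.numeric(mem_mat %*% w)
  best <- max(which(combined == max(combined)))   # severity tie-break
  row <- spec$levels[best, ]
  tibble::tibble(
    level = row$level, class = row$class, iec_class = row$iec_class,
    description = row$description,
    m_low = combined[1], m_moderate = combined[2], m_high = combined[3],
    m_extreme = combined[4],
    E_U_A = scores$score[scores$criterion == "U-A"],
    E_U_B = scores$score[scores$criterion == "U-B"],
    E_U_C = scores$score[scores$criterion == "U-C"],
    E_U_D = scores$score[scores$criterion == "U-D"])
}

#' Default leaf scoring of scenario measurements
#'
#' Maps a scenario's physical measurements onto the criterion score scales
#' by piecewise-linear transforms (the rubric is configurable; these
#' defaults are documented choices, not published calibrations):
#' * `U-A` leaves (scale 0--6): eye irradiance relative to the MPE —
#'   0 at zero, 4 (High boundary) at the MPE, 6 at twice the MPE.
#' * `U-B` leaves (scale 0--9): irradiance relative to the MPE — 0 at zero,
#'   6 at the MPE, 9 at three times the MPE.
#' * `U-C` leaves (scale 0--5): retinal spot diameter relative to the
#'   fovea diameter (`fovea_um`) — 4 when the spot fills the fovea, 5 when
#'   the detector is fully covered.
#' * `U-D` leaves (scale 0--5): occlusion angle relative to the target
#'   subtense — 4 when dazzle covers the target, 5 at twice the subtense.
#'
#' @param d_um Spot diameter, micrometres (`Inf` or `NA` = all covered).
#' @param p_mw_cm2 Eye irradiance, mW/cm².
#' @param u_deg Occlusion angle, degrees.
#' @param mpe_mw_cm2 MPE on the same scale (default: 0.25 s visible CW).
#' @param fovea_um Fovea diameter, micrometres.
#' @param target_deg Target subtense, degrees.
#' @param hierarchy A [grading_hierarchy()].
#' @return Named numeric vector of leaf scores.
#' @export
default_leaf_scores <- function(d_um, p_mw_cm2, u_deg,
                                mpe_mw_cm2 = mpe_visible_cw() / 10,
                                fovea_um = 1400, target_deg = 2.75,
                                hierarchy = grading_hierarchy()) {
  pl <- function(x, xs, ys) approx(xs, ys, xout = min(max(x, xs[1]), xs[length(xs)]))$y
  sa <- pl(p_mw_cm2, c(0, mpe_mw_cm2, 2 * mpe_mw_cm2), c(0, 4, 6))
  sb <- pl(p_mw_cm2, c(0, mpe_mw_cm2, 3 * mpe_mw_cm2), c(0, 6, 9))
  d_eff <- if (is.na(d_um) || !is.finite(d_um)) Inf else d_um
  sc <- if (is.infinite(d_eff)) 5 else pl(d_eff, c(0, fovea_um, 2 * fovea_um),
                                          c(0, 4, 5))
  sd_ <- pl(u_deg, c(0, target_deg, 2 * target_deg), c(0, 4, 5))
  leaves <- hierarchy_leaves(hierarchy)
  vals <- dplyr::case_when(
    startsWith(leaves, "A") ~ sa,
    startsWith(leaves, "B") ~ sb,
    startsWith(leaves, "C") ~ sc,
    TRUE ~ sd_)
  setNames(vals, leaves)
}

#' Grade a table of scenario measurements
#'
#' Tabular front end to the grey-AHP grading chain: for each row of
#' `measurements` (columns `D_um`, `P_mW_cm2`, `U_deg`, optionally explicit
#' leaf-score columns named as in [hierarchy_leaves()]), computes the
#' criterion scores, grey memberships and interference Level.
#'
#' @param measurements Data frame of scenario measurements; a `scene`
#'   column is carried through if present.
#' @param hierarchy A [grading_hierarchy()].
#' @param spec A [grey_class_spec()].
#' @param ... Passed to [default_leaf_scores()].
#' @return A tibble: input identifiers plus `E_U_A` ... `E_U_D`,
#'   memberships and `level`.
#' @examples
#' grade_scenarios(tibble::tibble(D_um = 70, P_mW_cm2 = 1.537, U_deg = 1.62))
#' @export
grade_scenarios <- function(measurements, hierarchy = grading_hierarchy(),
                            spec = grey_class_spec(), ...) {
  leaves <- hierarchy_leaves(hierarchy)
  explicit <- all(leaves %in% names(measurements))
  purrr::map_dfr(seq_len(nrow(measurements)), function(i) {
    row <- measurements[i, ]
    ls <- if (explicit) {
      unlist(row[leaves])
    } else {
      default_leaf_scores(row$D_um, row$P_mW_cm2, row$U_deg,
                          hierarchy = hierarchy, ...)
    }
    scores <- aggregate_scores(ls, hierarchy)
    res <- assign_level(scores, hierarchy, spec)
    id <- if ("scene" %in% names(row)) tibble::tibble(scene = row$scene)
          else tibble::tibble(scene = paste0("row", i))
    dplyr::bind_cols(id, res)
  })
}
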