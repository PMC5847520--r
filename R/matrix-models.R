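# Stage-structured projection matrices, eigen-analysis and the two-region
# metapopulation matrix.
#
# The life cycle is female-only with a pre-breeding census: the youngest
# tracked class is 1-year-olds, so first-year survival is folded into the
# fecundity term f. Stages are single years 1..4 plus the 5+ adult class:
#
#       [ 0    0    0    0    f  ]
#       [ s1   0    0    0    0  ]
#   A = [ 0    s1   0    0    0  ]
#       [ 0    0    s2   0    0  ]
#       [ 0    0    0    s2   s3 ]
#
# with s1 survival of 1-3 year olds, s2 of 3-5 year olds, s3 of adults (5+).

#' Vital rates of a regional vulture population
#'
#' @param s1 annual survival of 1-3 year old birds.
#' @param s2 annual survival of 3-5 year old birds.
#' @param s3 annual survival of adults (5+).
#' @param f fecundity: breeding propensity x (clutch size / 2) x hatching
#'   success x fledging success x first-year survival (female offspring per
#'   adult female surviving to age 1).
#' @param region optional region label.
#' @return An object of class `vital_rates`.
#' @export
vital_rates <- function(s1, s2, s3, f, region = NA_character_) {
  v <- c(s1 = s1, s2 = s2, s3 = s3, f = f)
  if (any(!is.finite(v))) stop("vital rates must be finite")
  if (any(v[1:3] < 0 | v[1:3] > 1)) stop("survival rates must lie in [0, 1]")
  if (f < 0) stop("fecundity must be non-negative")
  structure(list(s1 = s1, s2 = s2, s3 = s3, f = f, region = region),
            class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("Vital rates%s: s1 = %.4f, s2 = %.4f, s3 = %.4f, f = %.4f\n",
              if (is.na(x$region)) "" else paste0(" (", x$region, ")"),
              x$s1, x$s2, x$s3, x$f))
  invisible(x)
}

#' Build the 5x5 stage projection matrix
#'
#' @param v a [vital_rates()] object.
#' @return 5x5 matrix of class `stage_matrix`.
#' @examples
#' A <- stage_matrix(vital_rates(0.8, 0.9, 0.95, 0.08))
#' growth_rate(A)
#' @export
stage_matrix <- function(v) {
  stopifnot(inherits(v, "vital_rates"))
  A <- matrix(0, 5, 5)
  A[1, 5] <- v$f
  A[2, 1] <- v$s1
  A[3, 2] <- v$s1
  A[4, 3] <- v$s2
  A[5, 4] <- v$s2
  A[5, 5] <- v$s3
  dimnames(A) <- list(paste0("stage", 1:5), paste0("stage", 1:5))
  structure(A, class = c("stage_matrix", "matrix", "array"), vitals = v)
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat("Stage projection matrix (pre-breeding census), lambda =",
      format(growth_rate(x), digits = 6), "\n")
  print(unclass(x)[,])
  invisible(x)
}

#' Asymptotic population growth rate
#'
#' The dominant eigenvalue of a non-negative projection matrix; lambda > 1
#' means growth, lambda < 1 decline.
#'
#' @param A square non-negative matrix.
#' @return numeric scalar lambda.
#' @export
growth_rate <- function(A) {
  A <- as_projection(A)
  ev <- eigen(A, only.values = TRUE)$values
  # dominant eigenvalue of a primitive non-negative matrix is real (Perron)
  Re(ev[which.max(Mod(ev))])
}

as_projection <- function(A) {
  A <- unclass(A)
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("matrix must be square")
  if (any(!is.finite(A))) stop("matrix entries must be finite")
  if (any(A < 0)) stop("matrix entries must be non-negative")
  A
}

#' Eigen-analysis of a projection matrix
#'
#' Computes the demographic eigen-quantities: lambda, the stable stage
#' distribution `w` (right eigenvector, summing to 1), reproductive values
#' `v` (left eigenvector, scaled so stage 1 equals 1), the sensitivity
#' matrix `s_ij = v_i w_j / <v, w>` and the elasticity matrix
#' `e_ij = (a_ij / lambda) s_ij`. Elasticities over realized (non-zero)
#' entries sum to 1.
#'
#' @param A square non-negative matrix (e.g. a [stage_matrix()]).
#' @return list with `lambda`, `stable_stage`, `reproductive_value`,
#'   `sensitivity`, `elasticity`.
#' @export
eigen_analysis <- function(A) {
  M <- as_projection(A)
  er <- eigen(M)
  i <- which.max(Mod(er$values))
  lambda <- Re(er$values[i])
  if (abs(Im(er$values[i])) > 1e-8 * max(1, abs(lambda))) {
    stop("dominant eigenvalue is not real; matrix may be reducible or ",
         "imprimitive")
  }
  w <- Re(er$vectors[, i])
  if (sum(w) < 0) w <- -w
  if (any(w < -1e-8 * max(abs(w)))) {
    stop("dominant right eigenvector changes sign; matrix is reducible")
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  el <- eigen(t(M))
  j <- which.max(Mod(el$values))
  v <- Re(el$vectors[, j])
  if (v[1] < 0) v <- -v
  if (abs(v[1]) < 1e-12) stop("reproductive value of stage 1 is zero")
  v <- v / v[1]
  S <- (v %o% w) / sum(v * w)
  E <- (M / lambda) * S
  names(w) <- names(v) <- rownames(M)
  list(lambda = lambda, stable_stage = w, reproductive_value = v,
       sensitivity = S, elasticity = E)
}

#' @rdname eigen_analysis
#' @export
sensitivity_matrix <- function(A) eigen_analysis(A)$sensitivity

#' @rdname eigen_analysis
#' @export
elasticity_matrix <- function(A) eigen_analysis(A)$elasticity

#' @rdname eigen_analysis
#' @export
reproductive_values <- function(A) eigen_analysis(A)$reproductive_value

#' Published-style demographic table for the two regional populations
#'
#' The per-rate sensitivities, elasticities and reproductive values of the
#' two regional stage matrices as reported for the tagged populations
#' (Kruger growing at lambda = 1.04, KZN declining at lambda = 0.65),
#' together with those lambdas. These printed quantities are the inputs from
#' which [derive_vitals()] reconstructs the unpublished vital rates.
#'
#' @return list with elements `Kruger` and `KZN`, each a list holding
#'   `lambda` and a data frame with columns `parameter`, `sensitivity`,
#'   `elasticity`, `reproductive_value`.
#' @export
awbv_demography_table <- function() {
  pars <- c("s1_yr2", "s1_yr3", "s2_yr4", "s2_yr5", "s3", "f")
  list(
    Kruger = list(
      lambda = 1.04,
      table = data.frame(
        parameter = pars,
        sensitivity = c(0.038, 0.038, 0.035, 0.035, 0.879, 0.407),
        elasticity = c(0.030, 0.030, 0.030, 0.030, 0.849, 0.030),
        reproductive_value = c(1.000, 1.263, 1.595, 1.855, 2.158, NA))),
    KZN = list(
      lambda = 0.65,
      table = data.frame(
        parameter = pars,
        sensitivity = c(0.063, 0.063, 0.107, 0.107, 0.660, 0.710),
        elasticity = c(0.083, 0.083, 0.083, 0.083, 0.582, 0.083),
        reproductive_value = c(1.000, 0.758, 0.574, 0.734, 0.938, NA))))
}

#' Reconstruct vital rates from printed sensitivities and elasticities
#'
#' Inverts the elasticity definition `e_ij = (a_ij / lambda) s_ij` entry by
#' entry: `a_ij = e_ij lambda / s_ij`. Survival entries that invert to
#' slightly above 1 (printed-table rounding) are clipped to 1 with a
#' warning. Where a rate appears in several matrix positions (s1 in years
#' 2-3, s2 in years 4-5) the inverted values are averaged.
#'
#' @param lambda the published growth rate.
#' @param sensitivity,elasticity named numeric vectors over
#'   `c("s1_yr2", "s1_yr3", "s2_yr4", "s2_yr5", "s3", "f")`, or a data frame
#'   in the layout of [awbv_demography_table()] passed as `sensitivity`
#'   (then `elasticity` is ignored).
#' @param region optional label.
#' @return A [vital_rates()] object.
#' @examples
#' tab <- awbv_demography_table()$KZN
#' derive_vitals(tab$lambda, tab$table, region = "KZN")
#' @export
derive_vitals <- function(lambda, sensitivity, elasticity = NULL,
                          region = NA_character_) {
  if (lambda <= 0) stop("lambda must be positive")
  if (is.data.frame(sensitivity)) {
    tab <- sensitivity
    s <- stats::setNames(tab$sensitivity, tab$parameter)
    e <- stats::setNames(tab$elasticity, tab$parameter)
  } else {
    s <- sensitivity; e <- elasticity
  }
  pars <- c("s1_yr2", "s1_yr3", "s2_yr4", "s2_yr5", "s3", "f")
  if (!all(pars %in% names(s)) || !all(pars %in% names(e))) {
    stop("need sensitivity and elasticity for: ",
         paste(pars, collapse = ", "))
  }
  if (any(s[pars] == 0)) stop("zero sensitivity entry; cannot invert")
  a <- e[pars] * lambda / s[pars]
  clip <- function(x, nm) {
    if (x > 1) {
      warning(sprintf("%s inverts to %.4f > 1; clipped to 1 (printed-table ",
                      nm, x), "rounding)", call. = FALSE)
      1
    } else x
  }
  s1 <- clip(mean(a[c("s1_yr2", "s1_yr3")]), "s1")
  s2 <- clip(mean(a[c("s2_yr4", "s2_yr5")]), "s2")
  s3 <- clip(a[["s3"]], "s3")
  vital_rates(s1, s2, s3, a[["f"]], region = region)
}

#' Reconstructed vital rates for both regions
#'
#' Convenience wrapper applying [derive_vitals()] to the published
#' demographic table of each region.
#'
#' @return list with `vital_rates` objects `Kruger` and `KZN`.
#' @export
awbv_vital_rates <- function() {
  tabs <- awbv_demography_table()
  list(Kruger = suppressWarnings(
         derive_vitals(tabs$Kruger$lambda, tabs$Kruger$table,
                       region = "Kruger")),
       KZN = derive_vitals(tabs$KZN$lambda, tabs$KZN$table, region = "KZN"))
}

#' Two-region metapopulation projection matrix
#'
#' Combines the Kruger (upper-left block) and KZN (lower-right block) stage
#' matrices with symmetric dispersal: each life-cycle arc with rate `r`
#' splits into `r (1 - d)` staying in the source region and `r d` arriving
#' in the other region's corresponding stage, so column mass is conserved
#' (`within + cross = r`). First-year dispersal `gb0` / `bg0` applies to the
#' fecundity arcs, `gb` / `bg` to all survival arcs.
#'
#' @param v_kruger,v_kzn [vital_rates()] for the two regions.
#' @param gb dispersal fraction Kruger to KZN (survival arcs).
#' @param bg dispersal fraction KZN to Kruger (survival arcs).
#' @param gb0,bg0 first-year dispersal fractions applied to fecundity.
#' @return 10x10 matrix of class `metapop_matrix` (stages 1-5 Kruger,
#'   6-10 KZN).
#' @export
metapop_matrix <- function(v_kruger, v_kzn, gb = 0.02, bg = 0.02,
                           gb0 = 0.05, bg0 = 0.05) {
  stopifnot(inherits(v_kruger, "vital_rates"), inherits(v_kzn, "vital_rates"))
  d <- c(gb, bg, gb0, bg0)
  if (any(d < 0 | d > 1)) stop("dispersal fractions must lie in [0, 1]")
  arcs <- function(v, disp, disp0) {
    within <- matrix(0, 5, 5); cross <- matrix(0, 5, 5)
    put <- function(i, j, r, d0) {
      within[i, j] <<- r * (1 - d0)
      cross[i, j] <<- r * d0
    }
    put(1, 5, v$f, disp0)
    put(2, 1, v$s1, disp); put(3, 2, v$s1, disp)
    put(4, 3, v$s2, disp); put(5, 4, v$s2, disp)
    put(5, 5, v$s3, disp)
    list(within = within, cross = cross)
  }
  kr <- arcs(v_kruger, gb, gb0)
  kz <- arcs(v_kzn, bg, bg0)
  M <- matrix(0, 10, 10)
  M[1:5, 1:5] <- kr$within
  M[6:10, 1:5] <- kr$cross     # Kruger-born arcs arriving in KZN
  M[6:10, 6:10] <- kz$within
  M[1:5, 6:10] <- kz$cross     # KZN-born arcs arriving in Kruger
  dimnames(M) <- list(c(paste0("Kr", 1:5), paste0("Kz", 1:5)),
                      c(paste0("Kr", 1:5), paste0("Kz", 1:5)))
  structure(M, class = c("metapop_matrix", "matrix", "array"),
            dispersal = c(gb = gb, bg = bg, gb0 = gb0, bg0 = bg0),
            vitals = list(Kruger = v_kruger, KZN = v_kzn))
}

#' @export
print.metapop_matrix <- function(x, ...) {
  d <- attr(x, "dispersal")
  cat(sprintf(
    "Metapopulation matrix (Kruger block | KZN block), lambda = %.6f\n",
    growth_rate(x)))
  cat(sprintf("  dispersal: gb = %.3f, bg = %.3f, gb0 = %.3f, bg0 = %.3f\n",
              d["gb"], d["bg"], d["gb0"], d["bg0"]))
  print(round(unclass(x)[,], 4))
  invisible(x)
}
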