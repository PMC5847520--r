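#' @keywords internal
"_PACKAGE"

REGIONS <- c("Kruger", "KZN")
AGE_CLASSES <- c("juvenile", "subadult", "adult")

#' Capture-history set
#'
#' Container for annualized mark-resighting data: one row per tagged bird,
#' one 0/1 column per annual occasion, plus the region of tagging, the age
#' class at release and the release occasion. Entries before release are
#' structurally meaningless (the Cormack-Jolly-Seber likelihood conditions on
#' first capture) and are stored as 0.
#'
#' @param ch integer matrix of 0/1 detections, birds in rows, occasions in
#'   columns.
#' @param region character or factor, one of `"Kruger"`, `"KZN"` per bird.
#' @param age_at_release character or factor, one of `"juvenile"`,
#'   `"subadult"`, `"adult"` per bird.
#' @param release integer occasion index (1-based) at which each bird was
#'   tagged; `ch[i, release[i]]` must be 1.
#' @param bird_id optional character ids; generated when missing.
#' @return An object of class `capture_histories`.
#' @export
capture_histories <- function(ch, region, age_at_release, release,
                              bird_id = NULL) {
  ch <- as.matrix(ch)
  storage.mode(ch) <- "integer"
  n <- nrow(ch)
  if (n == 0L) stop("empty capture-history set")
  if (!all(ch %in% c(0L, 1L))) stop("detections must be 0/1")
  region <- factor(as.character(region), levels = REGIONS)
  age_at_release <- factor(as.character(age_at_release), levels = AGE_CLASSES)
  release <- as.integer(release)
  if (anyNA(region)) stop("unknown region label")
  if (anyNA(age_at_release)) stop("unknown age-class label")
  if (length(region) != n || length(age_at_release) != n ||
      length(release) != n) {
    stop("covariate lengths must match the number of histories")
  }
  if (any(release < 1L) || any(release > ncol(ch))) {
    stop("release occasion out of range")
  }
  if (any(ch[cbind(seq_len(n), release)] != 1L)) {
    stop("entry at the release occasion must be 1")
  }
  if (is.null(bird_id)) bird_id <- sprintf("bird%04d", seq_len(n))
  structure(
    list(ch = ch, region = region, age_at_release = age_at_release,
         release = release, bird_id = as.character(bird_id)),
    class = "capture_histories")
}

#' @export
print.capture_histories <- function(x, ...) {
  cat("Capture-history set:", nrow(x$ch), "birds,", ncol(x$ch),
      "annual occasions\n")
  cat("  regions:   ", paste(sprintf("%s=%d", levels(x$region),
                                     tabulate(x$region, 2L)),
                             collapse = ", "), "\n")
  cat("  age class: ", paste(sprintf("%s=%d", levels(x$age_at_release),
                                     tabulate(x$age_at_release, 3L)),
                             collapse = ", "), "\n")
  reseen <- sum(apply(x$ch, 1L, function(h) sum(h) > 1L))
  cat("  re-sighted at least once after release:", reseen, "\n")
  invisible(x)
}

#' @export
summary.capture_histories <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Number of birds and occasions
#' @param x a `capture_histories` object.
#' @export
dim.capture_histories <- function(x) dim(x$ch)

#' Age class of a bird a given number of years after release
#'
#' Age classes follow plumage-based field ageing: juveniles are first- and
#' second-year birds, subadults third- to fifth-year, adults six years and
#' older. A bird tagged in a class is taken to enter that class in its first
#' year, so class advances deterministically with elapsed years: a juvenile
#' turns subadult after 2 years and adult after 5; a subadult turns adult
#' after 3 years.
#'
#' @param age_at_release character vector of classes at tagging.
#' @param years_since non-negative integer vector (recycled) of elapsed years.
#' @return character vector of current classes.
#' @export
age_class_at <- function(age_at_release, years_since) {
  age_at_release <- as.character(age_at_release)
  n <- max(length(age_at_release), length(years_since))
  age_at_release <- rep_len(age_at_release, n)
  years_since <- rep_len(as.integer(years_since), n)
  if (any(years_since < 0L)) stop("years_since must be non-negative")
  # years of age at tagging implied by class entry: juvenile 1, subadult 3,
  # adult 6 (first year of each class)
  entry <- c(juvenile = 1L, subadult = 3L, adult = 6L)[age_at_release]
  age <- entry + years_since
  out <- character(n)
  out[age <= 2L] <- "juvenile"
  out[age >= 3L & age <= 5L] <- "subadult"
  out[age >= 6L] <- "adult"
  out
}

#' Write / read capture histories as CSV
#'
#' Serializes as one row per bird with columns `bird_id`, `region`,
#' `age_at_release`, `release_occasion`, then one 0/1 column per occasion
#' (`occ1`, `occ2`, ...). UTF-8, header mandatory.
#'
#' @param x a `capture_histories` object.
#' @param file path to a CSV file.
#' @return `write_capture_histories` returns `file` invisibly;
#'   `read_capture_histories` returns a `capture_histories` object.
#' @export
write_capture_histories <- function(x, file) {
  stopifnot(inherits(x, "capture_histories"))
  df <- data.frame(bird_id = x$bird_id,
                   region = as.character(x$region),
                   age_at_release = as.character(x$age_at_release),
                   release_occasion = x$release,
                   x$ch,
                   stringsAsFactors = FALSE)
  names(df)[-(1:4)] <- sprintf("occ%d", seq_len(ncol(x$ch)))
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_capture_histories
#' @export
read_capture_histories <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  occ_cols <- grep("^occ[0-9]+$", names(df), value = TRUE)
  if (length(occ_cols) == 0L) stop("no occasion columns (occ1, occ2, ...)")
  occ_cols <- occ_cols[order(as.integer(sub("^occ", "", occ_cols)))]
  capture_histories(as.matrix(df[occ_cols]),
                    region = df$region,
                    age_at_release = df$age_at_release,
                    release = df$release_occasion,
                    bird_id = df$bird_id)
}
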