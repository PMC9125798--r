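#' Construct a baleen hormone profile
#'
#' A hormone profile is one whale's testosterone (T) series, and optionally a
#' co-registered stable-nitrogen-isotope series, measured at uniformly spaced
#' drilling positions along a baleen plate. Position 0 is the most recently
#' grown baleen; position increases toward the tip, i.e. toward older growth.
#'
#' @param whale_id single character id.
#' @param positions numeric vector of drilling positions in cm, strictly
#'   increasing with uniform spacing.
#' @param testosterone numeric vector of T concentrations (ng immunoreactive
#'   hormone per g baleen powder), non-negative, same length as `positions`.
#' @param d15n optional numeric vector of nitrogen isotope ratios (permil);
#'   when supplied it must be complete (no `NA`) and of the same length.
#' @param gumline_cut logical; `TRUE` when the plate was cut at the gumline and
#'   lacks the embedded root (roughly one year of recent growth). Metadata
#'   only: it does not alter any computation.
#' @param spacing_tol absolute tolerance on spacing uniformity.
#' @return an object of class `hormone_profile`: a list with elements
#'   `whale_id`, `positions`, `testosterone`, `d15n` (or `NULL`),
#'   `gumline_cut` and `spacing_cm`.
#' @export
hormone_profile <- function(whale_id, positions, testosterone, d15n = NULL,
                            gumline_cut = FALSE, spacing_tol = 1e-9) {
  stopifnot(is.character(whale_id), length(whale_id) == 1L, nzchar(whale_id))
  positions <- as.numeric(positions)
  testosterone <- as.numeric(testosterone)
  n <- length(positions)
  if (n < 5L) {
    stop("profile '", whale_id, "': at least 5 samples are required (the ",
         "four-neighbour peak rule can never fire on fewer)", call. = FALSE)
  }
  if (length(testosterone) != n) {
    stop("profile '", whale_id, "': positions and testosterone lengths differ",
         call. = FALSE)
  }
  if (anyNA(positions) || anyNA(testosterone)) {
    stop("profile '", whale_id, "': missing values are not allowed",
         call. = FALSE)
  }
  d <- diff(positions)
  if (any(d <= 0)) {
    bad <- positions[which(d <= 0)[1L] + 1L]
    stop("profile '", whale_id, "': positions must be strictly increasing ",
         "(violation at ", bad, " cm)", call. = FALSE)
  }
  spacing <- d[1L]
  off <- which(abs(d - spacing) > spacing_tol)
  if (length(off)) {
    stop("profile '", whale_id, "': non-uniform spacing at position ",
         positions[off[1L] + 1L], " cm (expected spacing ", spacing, " cm)",
         call. = FALSE)
  }
  if (any(testosterone < 0)) {
    stop("profile '", whale_id, "': negative testosterone at position ",
         positions[which(testosterone < 0)[1L]], " cm", call. = FALSE)
  }
  if (!is.null(d15n)) {
    d15n <- as.numeric(d15n)
    if (length(d15n) != n) {
      stop("profile '", whale_id, "': d15n length differs from positions",
           call. = FALSE)
    }
    if (anyNA(d15n)) {
      stop("profile '", whale_id, "': d15n contains missing cells; a whale ",
           "either has a complete isotope series or none", call. = FALSE)
    }
  }
  structure(
    list(whale_id = whale_id, positions = positions,
         testosterone = testosterone, d15n = d15n,
         gumline_cut = isTRUE(gumline_cut), spacing_cm = spacing),
    class = "hormone_profile")
}

#' @export
print.hormone_profile <- function(x, ...) {
  cat("Baleen hormone profile '", x$whale_id, "'\n", sep = "")
  cat("  ", length(x$positions), " samples every ", x$spacing_cm,
      " cm, span ", min(x$positions), "-", max(x$positions), " cm\n", sep = "")
  cat("  T [ng/g]: ", signif(min(x$testosterone), 3), "-",
      signif(max(x$testosterone), 3),
      if (is.null(x$d15n)) "; no d15N series" else "; d15N series present",
      if (x$gumline_cut) "; gumline-cut plate" else "", "\n", sep = "")
  invisible(x)
}

#' Number of samples in a profile
#' @param profile a `hormone_profile`.
#' @return integer sample count.
#' @export
n_samples <- function(profile) length(profile$positions)

#' Restrict a profile to an analysis window
#'
#' Used when only part of a plate carries hormone cycles (e.g. a juvenile
#' acyclic segment at the old end of the plate): all downstream stages then
#' operate on the windowed profile.
#'
#' @param profile a `hormone_profile`.
#' @param start_cm,end_cm window bounds in cm, `0 <= start_cm < end_cm <=`
#'   plate length; samples with `start_cm <= position <= end_cm` are kept.
#' @return a `hormone_profile` restricted to the window.
#' @export
apply_window <- function(profile, start_cm, end_cm) {
  stopifnot(inherits(profile, "hormone_profile"),
            is.numeric(start_cm), is.numeric(end_cm))
  plate_end <- max(profile$positions)
  if (!(start_cm >= 0 && start_cm < end_cm && end_cm <= plate_end)) {
    stop("invalid analysis window [", start_cm, ", ", end_cm,
         "] for plate of length ", plate_end, " cm", call. = FALSE)
  }
  keep <- profile$positions >= start_cm & profile$positions <= end_cm
  hormone_profile(profile$whale_id, profile$positions[keep],
                  profile$testosterone[keep],
                  d15n = if (!is.null(profile$d15n)) profile$d15n[keep],
                  gumline_cut = profile$gumline_cut)
}

# 17 significant digits guarantee a lossless double -> text -> double
# round trip, which the write/read equality contract relies on.
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
}

#' Read whale hormone profiles from a tidy CSV
#'
#' Expects one row per (whale, position) with columns `whale_id`,
#' `position_cm`, `testosterone_ng_g` and optionally `d15n_permil`; an
#' optional `gumline_cut` column (constant within whale) is honoured. Rows
#' are sorted by position within whale and all profile invariants are
#' enforced.
#'
#' @param path path to a CSV file.
#' @return named list of [hormone_profile] objects, one per whale.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("whale_id", "position_cm", "testosterone_ng_g")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("profiles file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  ids <- unique(df$whale_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$whale_id == id, , drop = FALSE]
    rows <- rows[order(rows$position_cm), , drop = FALSE]
    d15n <- NULL
    if ("d15n_permil" %in% names(rows) && !all(is.na(rows$d15n_permil))) {
      d15n <- rows$d15n_permil
    }
    gum <- if ("gumline_cut" %in% names(rows)) {
      isTRUE(as.logical(rows$gumline_cut[1L]))
    } else FALSE
    hormone_profile(as.character(id), rows$position_cm,
                    rows$testosterone_ng_g, d15n = d15n, gumline_cut = gum)
  })
  names(out) <- ids
  out
}

#' Write whale hormone profiles to a tidy CSV
#'
#' Inverse of [read_profiles()]: `read_profiles(write_profiles(x))` recovers
#' `x` to full floating-point precision. Output is byte-stable for a fixed
#' input.
#'
#' @param profiles list of [hormone_profile] objects (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  header <- "whale_id,position_cm,testosterone_ng_g,d15n_permil,gumline_cut"
  lines <- character(0)
  for (p in profiles) {
    stopifnot(inherits(p, "hormone_profile"))
    if (grepl(",", p$whale_id, fixed = TRUE)) {
      stop("whale_id must not contain commas: ", p$whale_id, call. = FALSE)
    }
    nd <- if (is.null(p$d15n)) rep(NA_real_, n_samples(p)) else p$d15n
    lines <- c(lines, paste(p$whale_id, .fmt_num(p$positions),
                            .fmt_num(p$testosterone), .fmt_num(nd),
                            p$gumline_cut, sep = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Read a whale metadata table
#'
#' Columns: `whale_id`, `body_length_m`, `collection_month`,
#' `collection_year`; optional `baleen_length_cm`, `aar_age_yr` (eye-lens
#' aspartic-acid-racemization age), `length_age_yr` (body-length-derived
#' age), `age_override_yr` (sensitivity analyses) and `gumline_cut`.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with class `whale_metadata` prepended; optional
#'   age columns are filled with `NA` when absent from the file.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("whale_id", "body_length_m", "collection_month",
                "collection_year")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("baleen_length_cm", "aar_age_yr", "length_age_yr",
                "age_override_yr")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"gumline_cut" %in% names(df)) df$gumline_cut <- FALSE
  df$gumline_cut <- as.logical(df$gumline_cut)
  validate_metadata(df)
  class(df) <- c("whale_metadata", "data.frame")
  df
}

validate_metadata <- function(df) {
  if (anyDuplicated(df$whale_id)) {
    stop("duplicate whale_id in metadata", call. = FALSE)
  }
  if (any(!is.finite(df$body_length_m)) || any(df$body_length_m <= 0)) {
    bad <- df$whale_id[which(!(df$body_length_m > 0))[1L]]
    stop("metadata: body_length_m must be > 0 (whale '", bad, "')",
         call. = FALSE)
  }
  if (any(df$collection_month < 1 | df$collection_month > 12, na.rm = TRUE)) {
    stop("metadata: collection_month must be in 1..12", call. = FALSE)
  }
  for (col in c("aar_age_yr", "length_age_yr", "age_override_yr")) {
    v <- df[[col]]
    if (any(v <= 0, na.rm = TRUE)) {
      stop("metadata: ", col, " must be > 0 when present", call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a whale metadata table
#'
#' @param metadata a `whale_metadata` data frame (as from [read_metadata()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  cols <- c("whale_id", "body_length_m", "collection_month",
            "collection_year", "baleen_length_cm", "length_age_yr",
            "aar_age_yr", "age_override_yr", "gumline_cut")
  df <- as.data.frame(metadata)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) df[[col]] <- .fmt_num(df[[col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","),
               do.call(paste, c(unname(as.list(df)), sep = ","))),
             con, sep = "\n")
  invisible(path)
}
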