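#' Construct a titration series
#'
#' A titration series holds the observed 31P chemical shifts of the alpha-
#' and beta-phosphate peaks of one nucleotide sample series, at a single
#' ADP concentration, as a function of added Mg2+ equivalents
#' (chi_Mg = [Mg2+]/[ADP]).
#'
#' @param mg_equiv Numeric vector of Mg2+ equivalents, non-negative, unique.
#' @param delta_alpha Observed alpha-31P shifts, ppm. Finite.
#' @param delta_beta Observed beta-31P shifts, ppm, or `NA` when only one
#'   channel was recorded.
#' @param adp_conc ADP concentration, mM, positive scalar.
#' @param j_ab Optional 31P-31P scalar couplings, Hz.
#' @param nucleus_freq 31P Larmor frequency, MHz.
#' @param temperature Sample temperature, K.
#'
#' @return An object of class `titration_series`: a data.frame with columns
#'   `mg_equiv`, `delta_alpha`, `delta_beta`, `j_ab`, sorted by `mg_equiv`,
#'   carrying `adp_conc`, `nucleus_freq` and `temperature` attributes.
#' @examples
#' titration_series(c(0, 0.5, 1), c(-10.9, -10.5, -10.0),
#'                  c(-6.5, -6.3, -6.1), adp_conc = 10)
#' @export
titration_series <- function(mg_equiv, delta_alpha, delta_beta = NA_real_,
                             adp_conc, j_ab = NA_real_,
                             nucleus_freq = phos_constants()$nu0_31p_mhz,
                             temperature = phos_constants()$temperature_default) {
  mg_equiv <- as.numeric(mg_equiv)
  n <- length(mg_equiv)
  delta_alpha <- rep_len(as.numeric(delta_alpha), n)
  delta_beta <- rep_len(as.numeric(delta_beta), n)
  j_ab <- rep_len(as.numeric(j_ab), n)
  if (n == 0L) stop("titration series has zero points", call. = FALSE)
  if (anyNA(mg_equiv) || any(mg_equiv < 0)) {
    stop("mg_equiv must be non-negative and non-missing", call. = FALSE)
  }
  if (anyDuplicated(mg_equiv)) {
    stop("duplicate mg_equiv values: ",
         paste(unique(mg_equiv[duplicated(mg_equiv)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(adp_conc) || length(adp_conc) != 1L || !is.finite(adp_conc) ||
      adp_conc <= 0) {
    stop("adp_conc must be a positive scalar (mM)", call. = FALSE)
  }
  if (any(!is.finite(delta_alpha))) {
    stop("delta_alpha must be finite at every point", call. = FALSE)
  }
  if (any(!is.na(delta_beta) & !is.finite(delta_beta))) {
    stop("delta_beta must be finite where present", call. = FALSE)
  }
  ord <- order(mg_equiv)
  out <- data.frame(
    mg_equiv = mg_equiv[ord],
    delta_alpha = delta_alpha[ord],
    delta_beta = delta_beta[ord],
    j_ab = j_ab[ord]
  )
  structure(out,
            adp_conc = adp_conc,
            nucleus_freq = nucleus_freq,
            temperature = temperature,
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, [ADP] = %g mM, nu0 = %g MHz, T = %g K\n",
              nrow(x), attr(x, "adp_conc"), attr(x, "nucleus_freq"),
              attr(x, "temperature")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Parse a shift cell that may be a single value or a ";"-separated list of
# per-peak shifts (one per multiplet line); multiplets are summarized by the
# mean peak position.
parse_shift_cell <- function(x) {
  vapply(as.character(x), function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(NA_real_)
    vals <- suppressWarnings(as.numeric(strsplit(cell, ";", fixed = TRUE)[[1]]))
    if (anyNA(vals)) return(NaN) # marks an unparseable cell
    mean(vals)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a titration peak table from CSV
#'
#' Reads a comma-separated table of chemical shifts versus Mg2+ equivalents
#' into a [titration_series()]. Columns are mapped through
#' `config$columns`; shift cells may be single ppm values or
#' semicolon-separated per-peak lists, which are averaged (the multiplet
#' position is taken as the mean of its peaks). Unparseable rows are
#' reported by row number and dropped with a warning, never silently.
#'
#' @param path Path to a CSV file with a header row, '.' decimal, UTF-8.
#' @param config List with elements:
#'   \describe{
#'     \item{columns}{Named character vector mapping the required fields
#'       `mg_equiv` and `delta_alpha` (and optionally `delta_beta`, `j_ab`,
#'       `adp_conc`) to column names in the file.}
#'     \item{adp_conc}{ADP concentration in mM if not a column.}
#'     \item{nucleus_freq, temperature}{Optional overrides.}
#'   }
#' @return A validated [titration_series()], sorted by `mg_equiv`.
#' @export
read_titration_table <- function(path, config = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- config$columns
  default_cols <- c(mg_equiv = "mg_equiv", delta_alpha = "delta_alpha",
                    delta_beta = "delta_beta", j_ab = "j_ab",
                    adp_conc = "adp_conc")
  if (is.null(cols)) cols <- character(0)
  cols <- c(cols, default_cols[setdiff(names(default_cols), names(cols))])
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty titration table: ", path, call. = FALSE)
  for (field in c("mg_equiv", "delta_alpha")) {
    if (!cols[[field]] %in% names(raw)) {
      stop(sprintf("configuration error: column '%s' (mapped to field '%s') absent from %s",
                   cols[[field]], field, path), call. = FALSE)
    }
  }
  get_col <- function(field, parser) {
    nm <- cols[[field]]
    if (nm %in% names(raw)) parser(raw[[nm]]) else rep(NA_real_, nrow(raw))
  }
  mg <- suppressWarnings(as.numeric(raw[[cols[["mg_equiv"]]]]))
  da <- get_col("delta_alpha", parse_shift_cell)
  db <- get_col("delta_beta", parse_shift_cell)
  jj <- get_col("j_ab", function(x) suppressWarnings(as.numeric(x)))
  bad <- which(is.na(mg) | is.nan(da) | is.nan(db))
  if (length(bad) > 0L) {
    warning(sprintf("dropping %d unparseable row(s) in %s: rows %s",
                    length(bad), basename(path),
                    paste(bad, collapse = ", ")), call. = FALSE)
    keep <- setdiff(seq_len(nrow(raw)), bad)
    mg <- mg[keep]; da <- da[keep]; db <- db[keep]; jj <- jj[keep]
  }
  if (length(mg) == 0L) stop("no parseable rows in ", path, call. = FALSE)
  adp <- config$adp_conc
  if (is.null(adp)) {
    ac <- get_col("adp_conc", function(x) suppressWarnings(as.numeric(x)))
    if (all(is.na(ac))) {
      stop("configuration error: adp_conc given neither in config nor as a column",
           call. = FALSE)
    }
    adp <- unique(ac[!is.na(ac)])
    if (length(adp) != 1L) {
      stop("all points in a titration series must share adp_conc; found: ",
           paste(adp, collapse = ", "), call. = FALSE)
    }
  }
  titration_series(
    mg_equiv = mg, delta_alpha = da, delta_beta = db, j_ab = jj,
    adp_conc = adp,
    nucleus_freq = config$nucleus_freq %||% phos_constants()$nu0_31p_mhz,
    temperature = config$temperature %||% phos_constants()$temperature_default
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table to CSV at full float precision
#'
#' Numeric columns are serialized with the shortest representation that
#' round-trips an IEEE double exactly (`%.17g`), so
#' `read_result_table(write_result_table(x))` reproduces every numeric
#' value bit-identically. Missing values become empty cells, never zeros.
#'
#' @param results A data.frame (any of the package's result tables).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("refusing to write an empty result table",
                                call. = FALSE)
  ser <- lapply(results, function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) "" else sprintf("%.17g", v)
      }, character(1))
      # prefer the shortest of %.15g/%.16g/%.17g that still round-trips
      for (i in seq_along(col)) {
        if (is.na(col[i])) next
        for (digs in c("%.15g", "%.16g")) {
          cand <- sprintf(digs, col[i])
          if (as.numeric(cand) == col[i]) { out[i] <- cand; break }
        }
      }
      out
    } else {
      out <- as.character(col)
      out[is.na(out)] <- ""
      out
    }
  })
  tab <- as.data.frame(ser, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- names(results)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path CSV path.
#' @return A data.frame; columns that parse fully as numbers are numeric,
#'   empty cells are `NA`.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (nm in names(tab)) {
    col <- tab[[nm]]
    col[!nzchar(col)] <- NA
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == is.na(col))) tab[[nm]] <- num else tab[[nm]] <- col
  }
  tab
}

#' Packaged reference tables
#'
#' Loads the packaged fixture tables of alpha-beta 31P chemical-shift
#' differences (ppm) and two-bond 31P-31P J-couplings (Hz) versus Mg2+
#' equivalents at 10, 20 and 30 mM ADP.
#'
#' @param which `"shift_differences"` or `"j_couplings"`.
#' @return A data.frame with columns `adp_conc_mM`, `mg_equiv`, and either
#'   `delta_delta_ppm` or `j_ab_hz`.
#' @export
load_reference_table <- function(which = c("shift_differences", "j_couplings")) {
  which <- match.arg(which)
  fname <- switch(which,
                  shift_differences = "shift_differences_vs_mg.csv",
                  j_couplings = "j_couplings_vs_mg.csv")
  path <- system.file("extdata", fname, package = "phosbind", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
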