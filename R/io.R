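# Tabular input/output ----------------------------------------------------------

.egt_matrices <- c("plasma", "rbc", "blood")

#' Read a concentration-time CSV
#'
#' Reads and validates a tidy concentration table (UTF-8, header, '.'
#' decimal) with at least the columns \code{time_h}, \code{matrix} and
#' \code{concentration_uM}; extra identifier columns such as
#' \code{subject_id} or \code{dose_mg_per_day} pass through.  Unknown
#' matrix labels, non-numeric fields and negative concentrations are
#' rejected with the offending row named.  If \code{hct} is supplied and
#' the file carries \code{blood} rows with matching \code{plasma} rows but
#' no \code{rbc} rows, RBC concentrations are derived via
#' [egt_blood_to_rbc()].
#'
#' @param path CSV file path.
#' @param hct optional hematocrit for blood-to-RBC derivation.
#' @return validated data frame.
#' @export
egt_read_concentrations <- function(path, hct = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "matrix", "concentration_uM")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(d$time_h) || !is.numeric(d$concentration_uM)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$concentration_uM))) |
                   is.na(suppressWarnings(as.numeric(d$time_h))))
    stop("non-numeric time_h/concentration_uM at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!d$matrix %in% .egt_matrices)
  if (length(bad)) {
    stop("unknown matrix label '", d$matrix[bad[1]], "' at row ", bad[1],
         " (allowed: ", paste(.egt_matrices, collapse = ", "), ")", call. = FALSE)
  }
  bad <- which(d$concentration_uM < 0 | is.na(d$concentration_uM))
  if (length(bad)) {
    stop("negative or missing concentration at row ", bad[1], call. = FALSE)
  }
  if (!is.null(hct) && any(d$matrix == "blood") && !any(d$matrix == "rbc")) {
    key <- setdiff(names(d), c("matrix", "concentration_uM"))
    b <- d[d$matrix == "blood", ]
    p <- d[d$matrix == "plasma", ]
    m <- merge(b, p, by = key, suffixes = c("_blood", "_plasma"))
    if (nrow(m)) {
      rbc <- m[key]
      rbc$matrix <- "rbc"
      rbc$concentration_uM <- egt_blood_to_rbc(
        m$concentration_uM_blood, m$concentration_uM_plasma, hct)
      d <- rbind(d, rbc[names(d)])
    }
  }
  d
}

#' Write a concentration-time CSV
#'
#' @param x data frame (or \code{egt_sim}/\code{egt_cohort}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
egt_write_concentrations <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the dose-ranging table as CSV
#'
#' Lays the [egt_dose_table()] result out with one row per
#' (initial-condition block, dose) and one column per reporting week,
#' values rounded to three significant figures for reporting.
#'
#' @param tab an \code{egt_dose_table}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
egt_write_dose_table <- function(tab, path) {
  stopifnot(inherits(tab, "egt_dose_table"))
  weeks <- sort(unique(tab$week))
  combos <- unique(tab[, c("C_p0", "dose_mg")])
  if (nrow(tab) != nrow(combos) * length(weeks)) {
    stop("incomplete dose table: expected a full block x dose x week grid",
         call. = FALSE)
  }
  wide <- combos
  for (w in weeks) {
    sub <- tab[tab$week == w, ]
    idx <- match(paste(combos$C_p0, combos$dose_mg),
                 paste(sub$C_p0, sub$dose_mg))
    wide[[paste0("week", w)]] <- signif(sub$C_plasma_uM[idx], 3)
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records package version, date, seed, parameter digest and input-file
#' checksums as JSON so a run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param params an \code{egt_parameters} object.
#' @param seed seed used (or NULL).
#' @param inputs character vector of input file paths to checksum.
#' @param extra named list of additional fields.
#' @return the manifest list, invisibly.
#' @export
egt_write_manifest <- function(path, params = NULL, seed = NULL,
                               inputs = character(0), extra = list()) {
  man <- c(list(
    package = "egtpbpk",
    version = as.character(utils::packageVersion("egtpbpk")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = if (!is.null(params)) unclass(params),
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs))),
    extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
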