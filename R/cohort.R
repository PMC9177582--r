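#' Cohorts of diagnosis-time patient records
#'
#' A cohort is a data frame (class \code{cohort}) with one row per patient:
#' \code{patient_id}, \code{diameter_mm}, the four site flags \code{bone},
#' \code{lung}, \code{liver}, \code{brain} (0/1 metastasis status at
#' diagnosis), receptor statuses \code{er}, \code{pr}, \code{her2}
#' (\code{"pos"}/\code{"neg"}), and, once prepared, the derived
#' \code{subtype}, \code{state_index} and \code{tumor_age_years}. Provenance
#' (source, filters, simulation seed) is carried in the \code{"provenance"}
#' attribute.
#'
#' @name cohort
NULL

.COHORT_CSV_COLS <- c("patient_id", "diameter_mm", "met_bone", "met_lung",
                      "met_liver", "met_brain", "er", "pr", "her2")

as_cohort <- function(df, provenance = list()) {
  class(df) <- c("cohort", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat(sprintf("cohort of %d patients\n", nrow(x)))
  if (nrow(x)) {
    prev <- vapply(.SITES, function(s) mean(x[[s]]), numeric(1))
    cat("  site prevalence (%):",
        paste(sprintf("%s %.2f", .SITES, 100 * prev), collapse = ", "), "\n")
  }
  prov <- attr(x, "provenance")
  if (length(prov$source)) cat("  source:", prov$source, "\n")
  invisible(x)
}

normalize_receptor <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("pos", "positive", "+", "1")] <- "pos"
  out[x %in% c("neg", "negative", "-", "0")] <- "neg"
  out
}

#' Derive the molecular subtype from receptor statuses
#'
#' A tumor positive for either ER or PR is hormone-receptor (HR) positive;
#' crossed with HER2 status this gives the four subtypes
#' \code{"HR-/HER2+"}, \code{"HR+/HER2+"}, \code{"HR+/HER2-"},
#' \code{"HR-/HER2-"}.
#'
#' @param er,pr,her2 Receptor statuses, \code{"pos"}/\code{"neg"} (several
#'   spellings accepted); anything else yields \code{NA}.
#' @return Character vector of subtypes.
#' @examples
#' derive_subtype("pos", "neg", "neg") # "HR+/HER2-"
#' @export
derive_subtype <- function(er, pr, her2) {
  er <- normalize_receptor(er)
  pr <- normalize_receptor(pr)
  her2 <- normalize_receptor(her2)
  hr <- ifelse(er == "pos" | pr == "pos", "HR+",
               ifelse(er == "neg" & pr == "neg", "HR-", NA))
  # er/pr NA: still HR+ if the other is positive
  hr[is.na(hr) & (er %in% "pos" | pr %in% "pos")] <- "HR+"
  h2 <- ifelse(her2 == "pos", "HER2+", ifelse(her2 == "neg", "HER2-", NA))
  ifelse(is.na(hr) | is.na(h2), NA_character_, paste0(hr, "/", h2))
}

#' Subtype labels in a fixed order
#' @export
subtype_levels <- function() {
  c("HR-/HER2+", "HR+/HER2+", "HR+/HER2-", "HR-/HER2-")
}

#' Read a cohort CSV
#'
#' Expects columns \code{patient_id, diameter_mm, met_bone, met_lung,
#' met_liver, met_brain, er, pr, her2} (plus optional \code{subtype}).
#' \code{column_map} renames non-standard input columns, as
#' \code{c(standard_name = "name_in_file")}. Rows with an unparseable
#' diameter or site flag are dropped, with counts and reasons recorded in the
#' provenance.
#'
#' @param path CSV file.
#' @param column_map Optional named character vector of column renames.
#' @return A [cohort] data frame.
#' @export
read_cohort <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(raw))
        stop("mapped column not in file: ", column_map[[std]])
      names(raw)[names(raw) == column_map[[std]]] <- std
    }
  }
  missing <- setdiff(.COHORT_CSV_COLS, names(raw))
  if (length(missing))
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- data.frame(
    patient_id = as.character(raw$patient_id),
    diameter_mm = suppressWarnings(as.numeric(raw$diameter_mm)),
    bone = suppressWarnings(as.integer(raw$met_bone)),
    lung = suppressWarnings(as.integer(raw$met_lung)),
    liver = suppressWarnings(as.integer(raw$met_liver)),
    brain = suppressWarnings(as.integer(raw$met_brain)),
    er = as.character(raw$er), pr = as.character(raw$pr),
    her2 = as.character(raw$her2),
    stringsAsFactors = FALSE
  )
  if ("subtype" %in% names(raw)) df$subtype <- as.character(raw$subtype)
  bad_diam <- is.na(df$diameter_mm)
  bad_flag <- apply(df[.SITES], 1L,
                    function(r) any(is.na(r)) || !all(r %in% c(0L, 1L)))
  keep <- !(bad_diam | bad_flag)
  rejected <- list(`missing diameter` = sum(bad_diam),
                   `invalid metastasis flag` = sum(bad_flag & !bad_diam))
  if (any(!keep))
    message(sum(!keep), " row(s) rejected while reading ", path)
  as_cohort(df[keep, , drop = FALSE],
            provenance = list(source = path,
                              n_read = nrow(df),
                              rejected = rejected))
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]; derived columns are not written.
#'
#' @param cohort A [cohort].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(patient_id = cohort$patient_id,
                    diameter_mm = cohort$diameter_mm,
                    met_bone = cohort$bone, met_lung = cohort$lung,
                    met_liver = cohort$liver, met_brain = cohort$brain,
                    er = cohort$er, pr = cohort$pr, her2 = cohort$her2)
  if ("subtype" %in% names(cohort)) out$subtype <- cohort$subtype
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Apply the diagnosis-time inclusion filters
#'
#' Retains records with a known diameter in \code{(0, d_max]} mm, all four
#' metastasis statuses known (0/1), and an assignable molecular subtype.
#' Registry-extraction criteria (sex, age, histology, site recode, year of
#' diagnosis) are assumed applied upstream of the CSV. The count removed per
#' criterion is stored in the \code{filter_report} provenance entry.
#'
#' @param cohort A [cohort].
#' @param d_max Maximum tumor diameter, mm (default 100, the lethal size).
#' @return Filtered [cohort] with a \code{filter_report} in its provenance.
#' @export
apply_inclusion_filters <- function(cohort, d_max = 100) {
  df <- cohort
  report <- list()
  drop <- function(bad, why) {
    report[[why]] <<- sum(bad, na.rm = TRUE)
    df[!bad, , drop = FALSE]
  }
  df <- drop(is.na(df$diameter_mm) | df$diameter_mm <= 0,
             "missing or non-positive diameter")
  df <- drop(df$diameter_mm > d_max,
             sprintf("diameter > %g mm", d_max))
  known_flags <- apply(df[.SITES], 1L,
                       function(r) !any(is.na(r)) && all(r %in% c(0L, 1L)))
  df <- drop(!known_flags, "unknown metastasis status")
  sub <- if ("subtype" %in% names(df) && !all(is.na(df$subtype)))
    ifelse(is.na(df$subtype) | !df$subtype %in% subtype_levels(),
           derive_subtype(df$er, df$pr, df$her2), df$subtype)
  else derive_subtype(df$er, df$pr, df$her2)
  df <- drop(is.na(sub), "subtype not assignable")
  prov <- attr(cohort, "provenance")
  prov$filter_report <- report
  prov$d_max <- d_max
  as_cohort(df, prov)
}

#' Write the inclusion-filter report as JSON
#'
#' @param cohort A filtered [cohort] (from [apply_inclusion_filters()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(cohort, path) {
  report <- attr(cohort, "provenance")$filter_report
  if (is.null(report)) stop("cohort has no filter report; run apply_inclusion_filters() first")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assign states and tumor ages
#'
#' Derives, for every record, the molecular subtype (unless already present),
#' the state index implied by the four site flags, and the tumor age imputed
#' from diameter under the growth law. Must be run before likelihood
#' evaluation.
#'
#' @param cohort A filtered [cohort].
#' @param growth A [gompertz_params()] object.
#' @return The prepared [cohort].
#' @export
prepare_cohort <- function(cohort, growth = gompertz_params()) {
  df <- cohort
  if (!"subtype" %in% names(df) || anyNA(df$subtype))
    df$subtype <- derive_subtype(df$er, df$pr, df$her2)
  df$state_index <- state_index(df$bone, df$lung, df$liver, df$brain)
  n_clamped <- 0L
  df$tumor_age_years <- withCallingHandlers(
    diameter_to_age(df$diameter_mm, growth),
    warning = function(w) {
      n_clamped <<- n_clamped + 1L
      invokeRestart("muffleWarning")
    })
  prov <- attr(cohort, "provenance")
  prov$growth <- unclass(growth)
  if (n_clamped > 0) {
    ids <- df$patient_id[3 * log(df$diameter_mm / (growth$d0_um / 1000)) >=
                           growth$alpha / growth$beta]
    prov$clamped_patients <- ids
    message(length(ids),
            " patient(s) at/above the Gompertz asymptotic diameter; ",
            "age clamped (ids in provenance)")
  }
  as_cohort(df, prov)
}

#' Split a cohort by molecular subtype
#'
#' @param cohort A prepared [cohort] (or any cohort with derivable subtype).
#' @return Named list of cohorts, one per subtype present; records with an
#'   unknown subtype are excluded with a message.
#' @export
stratify_by_subtype <- function(cohort) {
  sub <- if ("subtype" %in% names(cohort)) cohort$subtype
         else derive_subtype(cohort$er, cohort$pr, cohort$her2)
  unknown <- is.na(sub)
  if (any(unknown))
    message(sum(unknown), " record(s) with unknown subtype excluded from stratification")
  df <- cohort[!unknown, , drop = FALSE]
  sub <- sub[!unknown]
  prov <- attr(cohort, "provenance")
  lapply(split(seq_len(nrow(df)), factor(sub, levels = subtype_levels()),
               drop = TRUE),
         function(idx) as_cohort(df[idx, , drop = FALSE], prov))
}

#' Percentage of a count relative to a total
#'
#' The bookkeeping used in cohort characteristic tables: \code{100 * count /
#' total}, rounded to \code{digits} decimals (e.g. 7094 bone-metastasis
#' patients of 317,166 is 2.2\%).
#'
#' @param count,total Non-negative counts.
#' @param digits Decimals to round to.
#' @export
prevalence_percent <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}

#' Summarize a cohort
#'
#' Counts and percentages per metastatic site, diameter-bin occupancy, state
#' occupancy, and subtype sizes.
#'
#' @param cohort A prepared [cohort].
#' @param bin_breaks Diameter bin edges, mm.
#' @return List with \code{n}, \code{site} (count + percent per site),
#'   \code{diameter_bins}, \code{states} (16 counts), \code{subtypes}.
#' @export
cohort_summary <- function(cohort, bin_breaks = c(0, 20, 40, 60, 80, 100)) {
  n <- nrow(cohort)
  site_counts <- vapply(.SITES, function(s) sum(cohort[[s]]), numeric(1))
  bins <- cut(cohort$diameter_mm, bin_breaks, right = FALSE)
  states <- if ("state_index" %in% names(cohort))
    tabulate(cohort$state_index, 16L)
  else tabulate(state_index(cohort$bone, cohort$lung, cohort$liver,
                            cohort$brain), 16L)
  list(
    n = n,
    site = data.frame(site = .SITES, count = site_counts,
                      percent = prevalence_percent(site_counts, n)),
    diameter_bins = table(bins),
    states = stats::setNames(states, paste0("state", 1:16)),
    subtypes = if ("subtype" %in% names(cohort)) table(cohort$subtype)
  )
}
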