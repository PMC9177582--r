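# The published transition list of the 16-state diagram, as (from, to,
# symbolic rate). Two entries of the printed caption are typographical
# errors and appear here corrected: 10 -> 13 adds the lung and must carry
# tulu (printed "tuli + luli"), and 15 -> 16 adds the bone and must carry
# tubo (printed "lubo", which is not among the six rates).
caption_edges <- function() {
  txt <- c(
    "1 2 tuli",  "1 3 tubr",  "1 4 tulu",  "1 5 tubo",
    "2 6 tulu",  "2 10 tubo", "2 11 tubr",
    "3 7 tubo",  "3 9 tulu",  "3 11 tuli",
    "4 6 tuli+luli", "4 8 tubo", "4 9 tubr+lubr",
    "5 7 tubr",  "5 8 tulu",  "5 10 tuli",
    "6 13 tubo", "6 15 tubr+lubr",
    "7 12 tuli", "7 14 tulu",
    "8 13 tuli+luli", "8 14 tubr+lubr",
    "9 14 tubo", "9 15 tuli+luli",
    "10 12 tubr", "10 13 tulu",
    "11 12 tubo", "11 15 tulu",
    "12 16 tulu", "13 16 tubr+lubr",
    "14 16 tuli+luli", "15 16 tubo"
  )
  parts <- strsplit(txt, " ")
  data.frame(from = as.integer(sapply(parts, `[`, 1)),
             to = as.integer(sapply(parts, `[`, 2)),
             expr = sapply(parts, `[`, 3),
             stringsAsFactors = FALSE)
}

# Reconstruct the index -> flags mapping from the edge list alone: the
# primary-rate symbol in each edge names the site that becomes positive.
derive_state_flags <- function(edges = caption_edges()) {
  site_of <- c(tubo = "bone", tulu = "lung", tuli = "liver", tubr = "brain")
  flags <- matrix(NA_integer_, 16, 4,
                  dimnames = list(NULL, c("bone", "lung", "liver", "brain")))
  flags[1, ] <- 0L
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      from <- edges$from[r]; to <- edges$to[r]
      if (anyNA(flags[from, ])) next
      primary <- sub("\\+.*", "", edges$expr[r])
      site <- site_of[[primary]]
      cand <- flags[from, ]
      stopifnot(cand[site] == 0L)  # single-site addition must be consistent
      cand[site] <- 1L
      if (anyNA(flags[to, ])) {
        flags[to, ] <- cand
        changed <- TRUE
      } else {
        stopifnot(identical(unname(flags[to, ]), unname(cand)))  # uniqueness
      }
    }
    if (!changed) break
  }
  flags
}

# A small prepared cohort built in code, with known flags and diameters.
make_test_cohort <- function() {
  df <- data.frame(
    patient_id = paste0("P", 1:6),
    diameter_mm = c(5, 10, 40, 15, 22, 60),
    bone = c(0, 1, 0, 1, 0, 0),
    lung = c(0, 0, 1, 0, 0, 1),
    liver = c(0, 0, 0, 0, 0, 1),
    brain = c(0, 1, 0, 0, 0, 0),
    er = c("pos", "neg", "pos", "neg", "pos", "neg"),
    pr = c("neg", "neg", "pos", "neg", "neg", "neg"),
    her2 = c("neg", "pos", "neg", "neg", "pos", "neg"),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = df$patient_id,
                       diameter_mm = df$diameter_mm,
                       met_bone = df$bone, met_lung = df$lung,
                       met_liver = df$liver, met_brain = df$brain,
                       er = df$er, pr = df$pr, her2 = df$her2),
            path, row.names = FALSE)
  coh <- read_cohort(path)
  unlink(path)
  prepare_cohort(apply_inclusion_filters(coh))
}

# Larger rates than the registry-scale defaults so small simulated cohorts
# carry enough metastasis events for fast fitting checks.
fast_theta <- function() {
  rate_vector(tubo = 0.05, tulu = 0.03, tuli = 0.015, tubr = 0.008,
              luli = 0.4, lubr = 0.15)
}
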