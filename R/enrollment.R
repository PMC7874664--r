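#' Simulate an enrollment table with protocol exclusions
#'
#' Builds a follow-up enrollment table in which a configurable number of
#' records violate each exclusion rule, for exercising
#' [filter_enrollment()]. Defaults mirror a typical single-centre flow:
#' 57 patients completing follow-up, of whom 2 had a disease other than
#' lung cancer, 1 underwent wedge resection, 1 was lost to follow-up and
#' 1 withdrew consent, leaving 52 analysable records.
#'
#' @param n_analyzed number of records passing every rule.
#' @param n_other_disease records with a non-lung-cancer diagnosis.
#' @param n_wedge_resection records whose procedure was a wedge resection.
#' @param n_lost_followup records lost to follow-up.
#' @param n_consent_withdrawn records that withdrew consent before the
#'   postoperative assessment.
#' @param n_prior_thoracic_surgery records with prior thoracic surgery
#'   (an eligibility exclusion; default 0).
#' @param rng_seed seed for shuffling row order.
#' @return a data frame with columns `id`, `age`, `diagnosis`, `procedure`,
#'   `lost_to_followup`, `consent_withdrawn`, `prior_thoracic_surgery`.
#' @export
simulate_enrollment <- function(n_analyzed = 52L,
                                n_other_disease = 2L,
                                n_wedge_resection = 1L,
                                n_lost_followup = 1L,
                                n_consent_withdrawn = 1L,
                                n_prior_thoracic_surgery = 0L,
                                rng_seed = 1L) {
  counts <- c(n_analyzed, n_other_disease, n_wedge_resection,
              n_lost_followup, n_consent_withdrawn, n_prior_thoracic_surgery)
  if (any(counts < 0L)) stopf("counts must be nonnegative")
  n <- sum(counts)
  df <- data.frame(
    id = sprintf("E%03d", seq_len(n)),
    age = 65L,
    diagnosis = "lung_cancer",
    procedure = "lobectomy",
    lost_to_followup = FALSE,
    consent_withdrawn = FALSE,
    prior_thoracic_surgery = FALSE,
    stringsAsFactors = FALSE
  )
  i <- n_analyzed
  take <- function(k) if (k > 0L) (i + 1L):(i + k) else integer(0)
  j <- take(n_other_disease); df$diagnosis[j] <- "benign_nodule"; i <- i + n_other_disease
  j <- take(n_wedge_resection); df$procedure[j] <- "wedge_resection"; i <- i + n_wedge_resection
  j <- take(n_lost_followup); df$lost_to_followup[j] <- TRUE; i <- i + n_lost_followup
  j <- take(n_consent_withdrawn); df$consent_withdrawn[j] <- TRUE; i <- i + n_consent_withdrawn
  j <- take(n_prior_thoracic_surgery); df$prior_thoracic_surgery[j] <- TRUE
  with_seed(rng_seed, df[sample.int(n), , drop = FALSE])
}

#' Apply the study exclusion rules to an enrollment table
#'
#' Keeps records that (i) carry a primary lung cancer diagnosis, (ii) did
#' not undergo wedge resection (an anatomic lobectomy or segmentectomy is
#' required for the prediction formulas to apply), (iii) completed
#' follow-up, (iv) did not withdraw consent, (v) had no prior thoracic
#' surgery, and (vi) were at least 20 years old.
#'
#' @param enrollment a data frame with the columns produced by
#'   [simulate_enrollment()].
#' @return the analysable subset, with an attribute `exclusions` — a data
#'   frame tabulating how many records each rule removed (a record failing
#'   several rules is counted once, under the first rule in the order
#'   above).
#' @examples
#' analyzed <- filter_enrollment(simulate_enrollment())
#' nrow(analyzed)          # 52
#' attr(analyzed, "exclusions")
#' @export
filter_enrollment <- function(enrollment) {
  need <- c("diagnosis", "procedure", "lost_to_followup",
            "consent_withdrawn", "prior_thoracic_surgery", "age")
  missing_cols <- setdiff(need, names(enrollment))
  if (length(missing_cols) > 0L)
    stopf("enrollment table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  rules <- list(
    other_disease = enrollment$diagnosis != "lung_cancer",
    wedge_resection = enrollment$procedure == "wedge_resection",
    lost_to_followup = enrollment$lost_to_followup,
    consent_withdrawn = enrollment$consent_withdrawn,
    prior_thoracic_surgery = enrollment$prior_thoracic_surgery,
    under_20 = enrollment$age < 20
  )
  excluded_by <- rep(NA_character_, nrow(enrollment))
  for (nm in names(rules)) {
    hit <- rules[[nm]] & is.na(excluded_by)
    excluded_by[hit] <- nm
  }
  kept <- enrollment[is.na(excluded_by), , drop = FALSE]
  tab <- table(factor(excluded_by, levels = names(rules)))
  attr(kept, "exclusions") <- data.frame(reason = names(tab),
                                         n = as.integer(tab),
                                         stringsAsFactors = FALSE)
  kept
}
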