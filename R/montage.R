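#' The 19-lead 10-20 montage and its four cortical regions
#'
#' The standard 19-electrode International 10-20 montage used by dry-electrode
#' resting EEG headsets, partitioned into the four cortical regions the
#' analysis aggregates over: frontal (7 leads, Fp1-F8), central (Cz to T4,
#' i.e. the motor-sensory strip), parietal (Pz to P4) and occipital
#' (P7/T5 to O2).  The occipital region is the reference region from which
#' the intrinsic alpha frequency is derived.
#'
#' The region lists form an exact partition of the 19 leads; the published
#' endpoint notation ("FP1 to F8", "P7 to O2") is ambiguous under a literal
#' contiguous 10-20 ordering, so the partition below is the unique consistent
#' reading given the stated frontal count of 7 (see the methods vignette).
#'
#' @return A tibble with columns `lead` (ordered 19 lead names) and `region`
#'   (factor with levels frontal, central, parietal, occipital).
#' @examples
#' montage_1020()
#' dplyr::count(montage_1020(), region)
#' @export
montage_1020 <- function() {
  tibble::tibble(
    lead = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
             "T3", "C3", "Cz", "C4", "T4",
             "P3", "Pz", "P4",
             "T5", "T6", "O1", "O2"),
    region = factor(
      c(rep("frontal", 7), rep("central", 5), rep("parietal", 3),
        rep("occipital", 4)),
      levels = c("frontal", "central", "parietal", "occipital")
    )
  )
}

#' @rdname montage_1020
#' @format NULL
#' @usage NULL
#' @export
eeg_regions <- function() levels(montage_1020()$region)

# modern/legacy 10-20 synonym table (modern name -> montage name)
lead_synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize lead labels onto the montage naming
#'
#' Case-insensitive matching with the modern temporal-lead synonyms
#' (T7/T3, T8/T4, P7/T5, P8/T6) accepted.
#'
#' @param labels Character vector of lead labels as found in a file.
#' @return Character vector of canonical montage lead names; unmatched labels
#'   become `NA`.
#' @examples
#' canonical_leads(c("t7", "FP1", "P8"))
#' @export
canonical_leads <- function(labels) {
  canon <- montage_1020()$lead
  lut <- setNames(canon, toupper(canon))
  syn <- setNames(unname(lut[toupper(lead_synonyms)]), toupper(names(lead_synonyms)))
  lut <- c(lut, syn)
  unname(lut[toupper(trimws(labels))])
}

#' Leads belonging to a cortical region
#'
#' @param region One of `"frontal"`, `"central"`, `"parietal"`, `"occipital"`.
#' @param montage Montage tibble as returned by [montage_1020()].
#' @return Character vector of lead names in montage order.
#' @examples
#' region_leads("frontal")   # the 7 frontal leads
#' region_leads("occipital")
#' @export
region_leads <- function(region, montage = montage_1020()) {
  region <- as.character(region)
  if (length(region) != 1L || !region %in% levels(montage$region)) {
    abort(sprintf("Unknown region '%s'; must be one of %s.",
                  paste(region, collapse = ","),
                  paste(levels(montage$region), collapse = ", ")))
  }
  montage$lead[montage$region == region]
}
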