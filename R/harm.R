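#' Source-reliability categories and Harm Scores
#'
#' News-source domains are rated on an ordinal Harm Score (HS) from 1 to 9 in
#' nine categories of increasing potential contribution to manipulative
#' information spreading: Scientific, Mainstream Media, Satire, Clickbait,
#' Other, Shadow, Political, Fake and Hoax, Conspiracy and Junk Science.
#' Content with HS >= 7 (Political, Fake and Hoax, Conspiracy and Junk
#' Science) is treated as potentially disinformative. Other and Shadow - both
#' of unknown reliability - are merged into a single "Other" category in the
#' working 8-category vocabulary.
#'
#' @param merged If `TRUE` (default) return the 8-category scheme with Shadow
#'   merged into Other; otherwise the raw 9-category scheme where Shadow
#'   retains its own score.
#' @return A data.frame with columns `category`, `harm_score`,
#'   `disinformative` (HS >= 7) and `classifiable` (member of the ratio
#'   denominator set, i.e. not Other/Shadow).
#' @export
harm_scheme <- function(merged = TRUE) {
  full <- data.frame(
    category = c("Scientific", "Mainstream Media", "Satire", "Clickbait",
                 "Other", "Shadow", "Political", "Fake and Hoax",
                 "Conspiracy and Junk Science"),
    harm_score = 1:9,
    stringsAsFactors = FALSE
  )
  if (merged) full <- full[full$category != "Shadow", ]
  full$disinformative <- full$harm_score >= 7
  full$classifiable <- !full$category %in% c("Other", "Shadow")
  rownames(full) <- NULL
  full
}

#' The 8 merged content categories
#' @return Character vector of category names in Harm-Score order.
#' @export
content_categories <- function() harm_scheme()$category

#' The potentially disinformative category set (Harm Score >= 7)
#' @return Character vector: Political, Fake and Hoax, Conspiracy and Junk Science.
#' @export
disinformative_categories <- function() {
  hs <- harm_scheme()
  hs$category[hs$disinformative]
}

#' The classifiable category set (ratio denominator; excludes "Other")
#' @return Character vector of the 7 categories with known reliability.
#' @export
classifiable_categories <- function() {
  hs <- harm_scheme()
  hs$category[hs$classifiable]
}

#' Classify a content category by Harm Score
#'
#' @param category Character vector of category names from the merged
#'   8-category vocabulary.
#' @return A data.frame with columns `category`, `harm_score`,
#'   `disinformative` (flag, `TRUE` iff Harm Score >= 7).
#' @export
classify_harm <- function(category) {
  hs <- harm_scheme()
  idx <- match(category, hs$category)
  if (anyNA(idx)) {
    stop("unknown content category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "))
  }
  data.frame(category = category, harm_score = hs$harm_score[idx],
             disinformative = hs$disinformative[idx],
             stringsAsFactors = FALSE)
}
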