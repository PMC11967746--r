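# Closed vocabularies for self-reported race and ethnicity.

#' Race categories recognized by the cohort schema
#'
#' US-convention self-reported race categories. Any raw value outside this
#' vocabulary (including missing) is coerced to `"Unknown"` at load time.
#'
#' @return Character vector of the eight race categories.
#' @export
race_levels <- function() {
  c(
    "American Indian and/or Alaska Native",
    "Asian",
    "Black or African",
    "Native Hawaiian or Pacific Islander",
    "White",
    "Mixed",
    "Other",
    "Unknown"
  )
}

#' Ethnicity categories recognized by the cohort schema
#'
#' @return Character vector of the three ethnicity categories.
#' @export
ethnicity_levels <- function() {
  c("Hispanic or Latino", "Non-Hispanic or non-Latino", "Unknown")
}

# UK raw label -> US-style race category, per the UK government's recommended
# grouping. Keys are normalized (lower case, squeezed whitespace).
.ukbb_map <- local({
  m <- c(
    "any other black background" = "Black or African",
    "african"                    = "Black or African",
    "black or black british"     = "Black or African",
    "caribbean"                  = "Black or African",
    "any other asian background" = "Asian",
    "asian or asian british"     = "Asian",
    "bangladeshi"                = "Asian",
    "chinese"                    = "Asian",
    "indian"                     = "Asian",
    "pakistani"                  = "Asian",
    "any other white background" = "White",
    "british"                    = "White",
    "irish"                      = "White",
    "white"                      = "White",
    "do not know"                = "Unknown",
    "prefer not to answer"       = "Unknown",
    "any other mixed background" = "Mixed",
    "mixed"                      = "Mixed",
    "white and asian"            = "Mixed",
    "white and black african"    = "Mixed",
    "white and black caribbean"  = "Mixed",
    "other ethnic group"         = "Other"
  )
  m
})

#' Harmonize UK Biobank ethnic-background labels to US-style race categories
#'
#' Maps the UK census-style ethnic background labels onto the US-convention
#' race vocabulary used throughout the package, following the UK government's
#' recommended grouping: Black backgrounds (African, Caribbean, Black or Black
#' British, any other Black background) to `"Black or African"`; Asian
#' backgrounds (including Chinese, Indian, Pakistani, Bangladeshi) to
#' `"Asian"`; white backgrounds (British, Irish, any other white background)
#' to `"White"`; mixed backgrounds to `"Mixed"`; "other ethnic group" to
#' `"Other"`; "do not know" / "prefer not to answer" to `"Unknown"`.
#'
#' The function is total: matching is case- and whitespace-insensitive, and
#' unrecognized labels map to `"Unknown"` with a warning. It is idempotent on
#' its own outputs (every US-style category maps to itself).
#'
#' @param raw_label Character vector of UK-convention labels.
#' @return Character vector of race categories from [race_levels()].
#' @examples
#' harmonize_ukbb_race(c("Caribbean", "white and Asian", "prefer not to answer"))
#' @export
harmonize_ukbb_race <- function(raw_label) {
  key <- tolower(gsub("\\s+", " ", trimws(as.character(raw_label))))
  out <- unname(.ukbb_map[key])
  # idempotence: already-harmonized categories pass through
  us <- match(key, tolower(race_levels()))
  out[is.na(out) & !is.na(us)] <- race_levels()[us[is.na(out) & !is.na(us)]]
  unknown <- is.na(out)
  if (any(unknown)) {
    bad <- unique(raw_label[unknown & !is.na(raw_label) & key != ""])
    if (length(bad)) {
      warning(sprintf(
        "unrecognized UK ethnic-background label(s) mapped to Unknown: %s",
        paste(utils::head(bad, 10), collapse = ", ")
      ), call. = FALSE)
    }
    out[unknown] <- "Unknown"
  }
  out
}
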