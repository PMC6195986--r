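#' Numerical cleft classification code
#'
#' Structured form of the four-region numerical cleft code: the regions, in
#' fixed order, are upper lip, primary palate, hard palate and soft palate.
#' Each region carries either a `(right, left)` pair of severity grades or a
#' single midline grade; grades are integers 0 (no cleft) to 3 (most
#' severe).
#'
#' @param upper_lip,primary_palate,hard_palate,soft_palate Either a length-2
#'   integer vector `(right, left)` or a single integer midline grade.
#' @return A `cleft_code` object.
#' @export
#' @examples
#' cleft_code(c(0, 3), c(0, 1), c(0, 0), c(0, 0))
#' cleft_code(c(0, 0), c(0, 0), 3, 3) # midline hard and soft palate cleft
cleft_code <- function(upper_lip = c(0L, 0L), primary_palate = c(0L, 0L),
                       hard_palate = c(0L, 0L), soft_palate = c(0L, 0L)) {
  regions <- list(upper_lip = upper_lip, primary_palate = primary_palate,
                  hard_palate = hard_palate, soft_palate = soft_palate)
  regions <- lapply(regions, function(g) {
    g <- as.integer(g)
    if (!length(g) %in% c(1L, 2L) || any(is.na(g)) || any(g < 0L) || any(g > 3L)) {
      abort_cleftmorph("each region needs one midline grade or a (right, left) pair, grades 0-3",
                       "cleftmorph_validation_error")
    }
    g
  })
  structure(regions, class = "cleft_code")
}

#' @export
print.cleft_code <- function(x, ...) {
  cat("<cleft_code>", encode_cleft_code(x), "\n")
  invisible(x)
}

#' @export
format.cleft_code <- function(x, ...) encode_cleft_code(x)

#' Encode a cleft code as its canonical string
#'
#' Per region, paired grades print as two digits (right then left) and a
#' midline grade as a single digit; the four region groups are joined by
#' plain hyphens (printed tables sometimes mix en-dashes in; the canonical
#' form uses only `-`).
#'
#' @param code A [cleft_code()].
#' @return A string such as `"03-01-00-00"` or `"00-00-3-3"`.
#' @export
encode_cleft_code <- function(code) {
  stopifnot(inherits(code, "cleft_code"))
  paste(vapply(code, function(g) paste(g, collapse = ""), character(1)),
        collapse = "-")
}

#' Parse a cleft code string
#'
#' Accepts four groups of one or two digits separated by hyphens or
#' en-dashes (both occur in print). Two-digit groups become `(right, left)`
#' pairs, one-digit groups midline grades.
#'
#' @param text Code string, e.g. `"33-33-33-33"` or `"00–00–3-3"`.
#' @return A [cleft_code()].
#' @export
parse_cleft_code <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  norm <- gsub("[–—]", "-", text)
  groups <- strsplit(norm, "-", fixed = TRUE)[[1]]
  if (length(groups) != 4L) {
    abort_cleftmorph(sprintf("expected 4 dash-separated groups, found %d in '%s'",
                             length(groups), text),
                     "cleftmorph_parse_error")
  }
  parsed <- vector("list", 4L)
  pos <- 1L
  for (i in seq_len(4L)) {
    g <- groups[i]
    if (!grepl("^[0-9]{1,2}$", g)) {
      abort_cleftmorph(sprintf("group %d ('%s', position %d) is not 1-2 digits",
                               i, g, pos),
                       "cleftmorph_parse_error")
    }
    digits <- as.integer(strsplit(g, "")[[1]])
    if (any(digits > 3L)) {
      abort_cleftmorph(sprintf("group %d ('%s', position %d): grade > 3", i, g, pos),
                       "cleftmorph_parse_error")
    }
    parsed[[i]] <- digits
    pos <- pos + nchar(g) + 1L
  }
  cleft_code(parsed[[1]], parsed[[2]], parsed[[3]], parsed[[4]])
}

#' Bundled case-series example data
#'
#' `example_cohort()` returns the hard-palate and cleft surface areas of a
#' ten-animal case series of purebred neonatal dogs with secondary-palate
#' clefts, suitable for exercising [cleft_percentage()] and
#' [build_report()]. `example_codes()` returns the corresponding diagnostic
#' codes as printed (note the mixed dash characters and the one midline
#' form), for the codec round trip.
#'
#' @return A tibble.
#' @export
example_cohort <- function() {
  tibble::tibble(
    dog_no = 1:10,
    breed = c("French Mastiff", "Golden Retriever", "West Highland White Terrier",
              "English Bulldog", "Basset Hound", "Yorkshire Terrier",
              "English Bulldog", "German Shepherd", "English Bulldog",
              "English Bulldog"),
    total_area_mm2 = c(572, 297, 142, 356, 313, 97, 352, 153, 351, 331),
    cleft_area_mm2 = c(62, 101, 79, 121, 188, 45, 113, 31, 168, 213)
  )
}

#' @rdname example_cohort
#' @export
example_codes <- function() {
  tibble::tibble(
    dog_no = 1:10,
    cleft_type = c("CL", rep("CP", 5), rep("CLP", 4)),
    code = c("03–01–00-00", "00–00–33-33", "00–00–33-33",
             "00–00–33-33", "00–00–3-3", "00–00–33-33",
             "03–03–03-03", "22–33–33-33", "33–33–33-33",
             "33–33–33-33")
  )
}
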