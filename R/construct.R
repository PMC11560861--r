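#' Describe the barcoded lentiviral cassette
#'
#' A construct spec records the layout of the clone-barcode cassette as it
#' appears on the cDNA read: a fixed upstream anchor, a random tag of
#' `tag_length` bases (the clone barcode), and a fixed downstream anchor,
#' together with the tolerances used during capture.
#'
#' The anchor sequences are vector sequence immediately flanking the random
#' tag and are always supplied per experiment; [default_construct()] ships
#' synthetic example anchors for simulations and tests only.
#'
#' @param upstream_anchor,downstream_anchor fixed DNA sequences (A/C/G/T,
#'   at least 12 bases each) flanking the tag on the read.
#' @param tag_length length of the random clone tag (default 20).
#' @param max_anchor_mismatches maximum substitutions tolerated per anchor
#'   when locating the cassette (default 1). Must be below a quarter of the
#'   shorter anchor length so anchors stay identifiable.
#' @param min_tag_qual minimum per-base Phred quality required across the
#'   tag for a capture to be accepted (default 20).
#' @param min_umi_support minimum number of distinct UMIs required to keep
#'   a clone tag in a cell (default 1).
#' @return an object of class `construct_spec` (a validated list).
#' @examples
#' spec <- construct_spec("ACCGGTCGCCACCATG", "GGATCCGCGGCCGCTT")
#' spec$tag_length
#' @export
construct_spec <- function(upstream_anchor, downstream_anchor,
                           tag_length = 20L, max_anchor_mismatches = 1L,
                           min_tag_qual = 20L, min_umi_support = 1L) {
  spec <- structure(
    list(upstream_anchor = toupper(upstream_anchor),
         downstream_anchor = toupper(downstream_anchor),
         tag_length = as.integer(tag_length),
         max_anchor_mismatches = as.integer(max_anchor_mismatches),
         min_tag_qual = as.integer(min_tag_qual),
         min_umi_support = as.integer(min_umi_support)),
    class = "construct_spec")
  validate_construct(spec)
  spec
}

#' @rdname construct_spec
#' @param spec object to validate.
#' @export
validate_construct <- function(spec) {
  assert_that(inherits(spec, "construct_spec") || is.list(spec),
              "construct spec must be a list")
  for (a in c("upstream_anchor", "downstream_anchor")) {
    s <- spec[[a]]
    assert_that(is.character(s) && length(s) == 1L && nchar(s) >= 12L,
                "%s must be a single DNA string of length >= 12", a)
    assert_that(grepl("^[ACGT]+$", s),
                "%s must contain only A/C/G/T (no N)", a)
  }
  assert_that(spec$tag_length > 0L, "tag_length must be positive")
  min_anchor <- min(nchar(spec$upstream_anchor), nchar(spec$downstream_anchor))
  assert_that(spec$max_anchor_mismatches >= 0L &&
                spec$max_anchor_mismatches < min_anchor / 4,
              "max_anchor_mismatches must be in [0, min(anchor length)/4)")
  assert_that(spec$min_tag_qual >= 0L, "min_tag_qual must be >= 0")
  assert_that(spec$min_umi_support >= 1L, "min_umi_support must be >= 1")
  invisible(spec)
}

#' @rdname construct_spec
#' @details `default_construct()` returns a spec with synthetic 16-base
#'   example anchors (a Kozak-like upstream and a cloning-site-like
#'   downstream sequence). They stand in for the experiment's real vector
#'   anchors, which are always a configuration input.
#' @export
default_construct <- function() {
  construct_spec("ACCGGTCGCCACCATG", "GGATCCGCGGCCGCTT")
}

#' Read a construct spec from JSON
#'
#' @param path JSON file with the fields of [construct_spec()].
#' @return a `construct_spec`.
#' @export
read_construct_json <- function(path) {
  assert_that(file.exists(path), "construct file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(construct_spec, x[intersect(names(x), names(formals(construct_spec)))])
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("construct_spec: <", x$upstream_anchor, ">[N",
      x$tag_length, "]<", x$downstream_anchor, ">\n", sep = "")
  cat("  max anchor mismatches:", x$max_anchor_mismatches,
      "| min tag Phred:", x$min_tag_qual,
      "| min UMI support:", x$min_umi_support, "\n")
  invisible(x)
}
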