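#' Parse a colon-separated allele field
#'
#' SSR genotype tables encode the allele fragment lengths (AFLs, in bp) called
#' at one marker for one sample as a colon-separated string, e.g. `"221:231"`.
#' A `"0"` (or an empty cell) encodes a null call: no amplification product was
#' scored at that marker. Homozygous calls may appear either as `"x:x"` or as
#' `"x:0"`; both normalise to the single-element set `{x}`, because copy number
#' is not observable from fragment sizing.
#'
#' @param x Character vector of allele fields.
#' @param context Optional string (e.g. `"row 3, column CH01h01"`) used to make
#'   malformed-field errors locatable.
#'
#' @return A list of the same length as `x`; each element is a sorted integer
#'   vector of distinct AFLs (length zero for a null call).
#'
#' @details AFLs must be integers in `[50, 600]` bp, the sizing range covered
#'   by standard capillary-electrophoresis ladders; anything else is an error,
#'   not a warning, since out-of-range values indicate a scoring or transcription
#'   problem upstream.
#'
#' @examples
#' parse_allele_field(c("221:231", "0", "109:115:150"))
#' @export
parse_allele_field <- function(x, context = NULL) {
  purrr::map(as.character(x), parse_one_allele_field, context = context)
}

parse_one_allele_field <- function(text, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  if (is.na(text) || text == "" || text == "0") {
    return(integer(0))
  }
  tokens <- strsplit(text, ":", fixed = TRUE)[[1]]
  tokens <- tokens[tokens != ""]
  if (!all(grepl("^[0-9]+$", tokens))) {
    abort(sprintf("malformed allele field '%s'%s: non-integer token", text, where),
          class = "ssr_malformed_field")
  }
  vals <- as.integer(tokens)
  vals <- unique(vals[vals != 0L])  # "x:0" means the second allele was not scored
  if (length(vals) == 0L) {
    return(integer(0))
  }
  if (any(vals < 50L | vals > 600L)) {
    abort(sprintf(
      "malformed allele field '%s'%s: AFL outside plausible sizing range [50, 600] bp",
      text, where), class = "ssr_malformed_field")
  }
  sort(vals)
}

#' Serialize an allele set back to the colon-separated field format
#'
#' Inverse of [parse_allele_field()]: a sorted ascending `"a:b"` string, with
#' `"0"` for a null call.
#'
#' @param alleles A list of integer vectors (or a single integer vector).
#' @return Character vector of allele fields.
#' @examples
#' format_allele_field(list(c(221L, 231L), integer(0)))
#' @export
format_allele_field <- function(alleles) {
  if (!is.list(alleles)) alleles <- list(alleles)
  purrr::map_chr(alleles, function(a) {
    if (length(a) == 0L) "0" else paste(sort(as.integer(a)), collapse = ":")
  })
}

# Canonical internal form of an allele set: sorted unique integer vector.
as_allele_set <- function(a) {
  if (length(a) == 0L) return(integer(0))
  sort(unique(as.integer(a)))
}

# Key usable for hashing / tallying observed calls.
call_key <- function(a) format_allele_field(list(a))
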