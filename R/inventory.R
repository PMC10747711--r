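#' TIMIT phone inventory with CTC special tokens
#'
#' Constructs the phone inventory used throughout the aligner: the set of
#' ARPABET phone labels plus the three CTC special tokens (pad, unknown,
#' word delimiter) that a recognizer emits between phones. Each phone is
#' also assigned a unique Unicode codepoint starting at U+1F600; the
#' codepoint map is carried as metadata only (some CTC tokenizers require
#' single-codepoint symbols) and every public API works on ARPABET strings.
#'
#' @param phones character vector of ARPABET phone labels. Defaults to the
#'   full 61-phone TIMIT set (closures, `h#` silence, `epi`, `pau`
#'   included).
#' @param pad,unknown,delimiter the special token spellings.
#' @return an object of class `phone_inventory`: a list with elements
#'   `phones`, `special_tokens` (named character vector) and
#'   `codepoint_map` (named integer vector of Unicode codepoints).
#' @examples
#' inv <- phone_inventory()
#' length(inv$phones)              # 61
#' inv$special_tokens[["pad"]]     # "[pad]"
#' @export
phone_inventory <- function(phones = timit_phones(),
                            pad = "[pad]", unknown = "[unk]",
                            delimiter = "|") {
  phones <- as.character(phones)
  if (anyDuplicated(phones)) stop("phone labels must be unique")
  special <- c(pad = pad, unknown = unknown, delimiter = delimiter)
  if (any(special %in% phones))
    stop("special tokens must not collide with phone labels")
  codepoints <- 0x1F600L + seq_along(phones) - 1L
  names(codepoints) <- phones
  structure(
    list(phones = phones, special_tokens = special,
         codepoint_map = codepoints),
    class = "phone_inventory"
  )
}

#' The 61-phone TIMIT ARPABET label set
#'
#' @return character vector of 61 ARPABET labels, including stop closures
#'   (`bcl`, `tcl`, ...), silence `h#`, pause `pau` and epenthetic
#'   silence `epi`.
#' @export
timit_phones <- function() {
  c("aa", "ae", "ah", "ao", "aw", "ax", "ax-h", "axr", "ay",
    "b", "bcl", "ch", "d", "dcl", "dh", "dx",
    "eh", "el", "em", "en", "eng", "epi", "er", "ey",
    "f", "g", "gcl", "h#", "hh", "hv",
    "ih", "ix", "iy", "jh", "k", "kcl", "l", "m", "n", "ng", "nx",
    "ow", "oy", "p", "pau", "pcl", "q", "r", "s", "sh",
    "t", "tcl", "th", "uh", "uw", "ux", "v", "w", "y", "z", "zh")
}

#' @export
print.phone_inventory <- function(x, ...) {
  cat("<phone_inventory> ", length(x$phones), " phones; specials: ",
      paste(x$special_tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

is_special <- function(labels, inventory) {
  labels %in% inventory$special_tokens
}
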