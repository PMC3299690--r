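#' Ordered state alphabets for structural characters
#'
#' Phylogenetic software that handles ordered multistate characters caps the
#' number of states; lengths of RNA substructures are therefore coded on a
#' 64-symbol ordered alphabet (digits, upper-case letters, lower-case letters,
#' then `@` and `&`), and genomic-abundance census characters on a 21-symbol
#' alphabet (`0`-`9` then `A`-`K`). In both, the first symbol is the minimum
#' state and the last the maximum.
#'
#' @return A character vector of symbols in ascending state order.
#' @examples
#' rna_state_alphabet()[c(1, 11, 64)] # "0" "A" "&"
#' census_alphabet()[21]              # "K"
#' @export
rna_state_alphabet <- function() {
  c(as.character(0:9), LETTERS, letters, "@", "&")
}

#' @rdname rna_state_alphabet
#' @export
census_alphabet <- function() {
  c(as.character(0:9), LETTERS[1:11])
}

#' Encode a substructure length as an ordered state symbol
#'
#' Lengths map directly onto alphabet indices; anything at or beyond the last
#' index saturates at the maximum state `&`, and an absent substructure
#' (length 0) takes the minimum state `0`. The map is total and monotone.
#'
#' @param len Non-negative integer length(s) (base pairs for stems,
#'   nucleotides otherwise).
#' @param cap_at Index of the saturating state (default 63, the last symbol).
#' @return Character vector of state symbols.
#' @examples
#' encode_length(c(0, 10, 61, 62, 100)) # "0" "A" "z" "@" "&"
#' @export
encode_length <- function(len, cap_at = 63L) {
  if (any(is.na(len)) || any(len < 0)) {
    stop("lengths must be non-negative integers", call. = FALSE)
  }
  ab <- rna_state_alphabet()
  ab[pmin(as.integer(len), as.integer(cap_at)) + 1L]
}

#' Map state symbols back to 0-based alphabet indices
#'
#' @param symbols Character vector of symbols.
#' @param alphabet Alphabet to decode against (default the 64-state RNA one).
#' @return Integer vector of 0-based indices.
#' @export
symbol_index <- function(symbols, alphabet = rna_state_alphabet()) {
  idx <- match(symbols, alphabet)
  if (anyNA(idx) && !all(symbols[is.na(idx)] %in% c("?", NA))) {
    bad <- unique(symbols[is.na(idx) & !symbols %in% c("?")])
    stop("symbols outside alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx - 1L
}

#' Gap-code a genomic abundance value into 21 ordered states
#'
#' Abundances `g` vary over orders of magnitude; gap coding compresses them to
#' a 0-20 scale with `state = round(20 * ln(g + 1) / ln(g_max + 1))`, where
#' `g_max` is the largest abundance in the same proteome and rounding is
#' half-up. `g = 0` maps to state 0 and `g = g_max` to state 20 ('K').
#'
#' @param g Non-negative integer abundance(s).
#' @param g_max Maximum abundance in the proteome (>= 1).
#' @param method `"log"` (default) or `"linear"` (`round(20 * g / g_max)`).
#' @return Integer states in 0..20.
#' @examples
#' gap_code(c(0, 10, 1000), g_max = 1000) # 0 7 20
#' @export
gap_code <- function(g, g_max, method = c("log", "linear")) {
  method <- match.arg(method)
  if (any(g < 0) || any(g > g_max)) {
    stop("abundances must satisfy 0 <= g <= g_max", call. = FALSE)
  }
  if (g_max < 1) stop("g_max must be >= 1", call. = FALSE)
  x <- if (method == "log") 20 * log(g + 1) / log(g_max + 1) else 20 * g / g_max
  as.integer(floor(x + 0.5)) # half-up, not banker's rounding
}
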