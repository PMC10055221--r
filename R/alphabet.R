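#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in fixed alphabetical order
#' (A C D E F G H I K L M N P Q R S T V W Y). Every 20-way probability vector
#' in the package is indexed in this order, and prediction tables serialize
#' their probability columns in this order (`p_A` ... `p_Y`), so files are
#' self-describing.
#'
#' @return character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Default amino-acid class map
#'
#' Coarse biochemical grouping used to stratify accuracy: aliphatic
#' (A V L I M), aromatic (F W Y), polar (S T N Q C), positively charged
#' (K R H), negatively charged (D E), and the conformationally "unique"
#' pair (G P). Histidine sits in `positive` by default; pass your own map
#' to any function accepting `class_map` to move it (or to swap in another
#' scheme entirely).
#'
#' @return named character vector: names are the 20 amino acids, values are
#'   class labels from `aliphatic, aromatic, polar, positive, negative,
#'   unique`.
#' @export
#' @examples
#' table(aa_class_map())
aa_class_map <- function() {
  c(A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
    M = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    G = "unique", P = "unique")[aa_alphabet()]
}

aa_class_labels <- function() {
  c("aliphatic", "aromatic", "polar", "positive", "negative", "unique")
}

check_class_map <- function(class_map) {
  if (!is.character(class_map) || is.null(names(class_map)) ||
      !setequal(names(class_map), aa_alphabet()) ||
      anyNA(class_map)) {
    missing <- setdiff(aa_alphabet(), names(class_map))
    stop_resstack("resstack_config_error",
                  "class map must cover all 20 amino acids (missing: %s)",
                  paste(missing, collapse = ", "))
  }
  class_map[aa_alphabet()]
}
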