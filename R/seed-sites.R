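#' Scan a 3'UTR for canonical miRNA seed-match sites
#'
#' Classifies target sites by the canonical hierarchy used for seed-based
#' target prediction. The seed is miRNA nucleotides 2-7 (5'->3'). A UTR locus
#' is a `6mer` when it is the exact reverse complement of the seed; `7mer-m8`
#' additionally pairs miRNA position 8 at the 5' flank of the locus;
#' `7mer-A1` has an adenine in the UTR opposite miRNA position 1 at the 3'
#' flank; `8mer` satisfies both. Each 6mer locus is reported once with its
#' strongest type (8mer > 7mer-m8 > 7mer-A1 > 6mer). Only strict
#' Watson-Crick pairs count by default; G:U wobble can be permitted.
#'
#' @param mirna_seq miRNA sequence, 5'->3', RNA alphabet `ACGU`, length >= 8.
#' @param utr_seq UTR sequence, 5'->3', RNA alphabet.
#' @param allow_wobble also accept G:U pairs when matching (default FALSE).
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   coordinates of the full site on the UTR) and `site_type`; zero rows when
#'   no site exists.
#' @examples
#' scan_seed_sites("UGAGGUAGUAGGUUGU", "AAACUACCUCAAAA")
#' @export
scan_seed_sites <- function(mirna_seq, utr_seq, allow_wobble = FALSE) {
  mirna <- check_rna(mirna_seq, "mirna_seq")
  utr <- check_rna(utr_seq, "utr_seq")
  if (length(mirna) < 8L) stop("miRNA must be at least 8 nt")

  pairs_with <- function(utr_base, mirna_base) {
    wc <- c(A = "U", C = "G", G = "C", U = "A")
    ok <- utr_base == wc[[mirna_base]]
    if (allow_wobble)
      ok <- ok || (utr_base == "U" && mirna_base == "G") ||
            (utr_base == "G" && mirna_base == "U")
    ok
  }

  seed <- mirna[2:7]           # matched by UTR positions i+5 .. i (3'->5')
  n <- length(utr)
  out <- list()
  for (i in seq_len(max(0L, n - 5L))) {       # 1-based start of the 6mer core
    core <- utr[i:(i + 5L)]
    # UTR runs 5'->3'; the miRNA seed pairs antiparallel, so seed position 2
    # pairs the 3'-most core base.
    core_ok <- all(vapply(1:6, function(k)
      pairs_with(core[7L - k], mirna[k + 1L]), logical(1)))
    if (!core_ok) next
    m8 <- i > 1L && pairs_with(utr[i - 1L], mirna[8L])
    a1 <- (i + 6L) <= n && utr[i + 6L] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
            if (a1) "7mer-A1" else "6mer"
    start0 <- (i - 1L) - (if (m8) 1L else 0L)
    end0 <- (i - 1L) + 6L + (if (a1) 1L else 0L)
    out[[length(out) + 1L]] <- data.frame(start = start0, end = end0,
                                          site_type = type,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

check_rna <- function(seq, what) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
  if (length(bad))
    stop(what, ": invalid RNA characters: ", paste(bad, collapse = ", "))
  chars
}
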