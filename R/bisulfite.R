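.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' In-silico bisulphite conversion
#'
#' Bisulphite treatment converts unmethylated cytosine to uracil (read as
#' thymine) while 5-methylcytosine, found almost exclusively at CpG sites,
#' is protected. On the methylated template every CpG cytosine is retained
#' and every non-CpG (CH) cytosine becomes T; on the unmethylated template
#' every cytosine converts. Bottom-strand conversion reverse-complements the
#' input first and then applies the same rule. A terminal cytosine whose
#' next base is unknown (sequence end, or followed by N) cannot be called
#' CpG and is treated as converting, with a flag on the result.
#'
#' @param seq Uppercase A/C/G/T/N string (reference, unconverted).
#' @param methylation_state `"methylated"` or `"unmethylated"`.
#' @param strand `"top"` or `"bottom"`.
#' @return Object of class `converted_template`: list with `seq` (converted
#'   string, same length), `strand`, `methylation_state`, `cpg_positions`
#'   (1-based positions of retained CpG cytosines in converted coordinates),
#'   `source_seq` (the strand-oriented unconverted sequence) and
#'   `ambiguous_terminal_c` (logical flag).
#' @examples
#' bisulfite_convert("ACGGACCGA", "methylated")$seq    # "ACGGATCGA"
#' bisulfite_convert("ACGGACCGA", "unmethylated")$seq  # "ATGGATTGA"
#' @export
bisulfite_convert <- function(seq,
                              methylation_state = c("methylated",
                                                    "unmethylated"),
                              strand = c("top", "bottom")) {
  methylation_state <- match.arg(methylation_state)
  strand <- match.arg(strand)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("invalid character in sequence (A/C/G/T/N only)", call. = FALSE)
  }
  if (strand == "bottom") seq <- .revcomp(seq)
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  is_c <- bases == "C"
  next_base <- c(bases[-1], NA_character_)
  is_cpg <- is_c & !is.na(next_base) & next_base == "G"
  ambiguous <- is_c & (is.na(next_base) | next_base == "N")
  retained <- if (methylation_state == "methylated") is_cpg else rep(FALSE, n)
  bases[is_c & !retained] <- "T"
  structure(list(seq = paste(bases, collapse = ""), strand = strand,
                 methylation_state = methylation_state,
                 cpg_positions = which(retained),
                 source_seq = seq,
                 ambiguous_terminal_c = any(ambiguous)),
            class = "converted_template")
}

#' @export
print.converted_template <- function(x, ...) {
  cat(sprintf("<converted_template> %s strand, %s, %d bp, %d CpG retained\n",
              x$strand, x$methylation_state, nchar(x$seq),
              length(x$cpg_positions)))
  invisible(x)
}
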