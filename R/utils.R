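#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats p.adjust rlnorm runif sd setNames wilcox.test cmdscale
#' @importFrom utils head read.delim write.table
NULL

# fail with a classed condition so tests can target our errors specifically
mc_stop <- function(..., class = "metacompare_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

mc_warn <- function(...) warning(paste0(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# stage-count logging used by the analysis drivers; silent unless enabled
mc_log <- function(...) {
  if (isTRUE(getOption("metacompare.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

NUC_ALPHABET <- c("A", "C", "G", "T", "N")

check_nucleotide <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    mc_stop(what, " contains non-nucleotide characters (allowed: A,C,G,T,N): ",
            paste(head(names(seqs)[bad], 3L), collapse = ", "))
  }
  invisible(TRUE)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
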