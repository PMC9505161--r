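# Shared constants and tiny sequence helpers (loaded first).

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse complement of a plain character string
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# edited-base label on the transcript: T is written U
rna_base <- function(b) ifelse(b == "T", "U", b)

edit_type_label <- function(ref_sense, edit_sense) {
  paste0(rna_base(ref_sense), "-to-", rna_base(edit_sense))
}
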