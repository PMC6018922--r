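# shared fixture builders; everything is generated in code at test time

make_genes <- function(n, lengths = NULL, gc = NULL, seed = 42L) {
  set.seed(seed)
  if (is.null(lengths)) lengths <- sample(800:3000, n, replace = TRUE)
  if (is.null(gc)) gc <- runif(n, 0.38, 0.78)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             family_id = "fam", length_bp = as.integer(lengths),
             gc_fraction = gc, stringsAsFactors = FALSE)
}

write_fasta <- function(entries, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

# minimal valid SAM file; rname "*" with flag 4 is an unmapped record
write_sam <- function(targets, records, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
  body <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    mapped <- !is.na(r)
    paste(sprintf("r%03d", i), if (mapped) 0L else 4L,
          if (mapped) r else "*", if (mapped) 1L else 0L,
          if (mapped) 42L else 0L, if (mapped) "10M" else "*",
          "*", 0, 0, "ACGTACGTAC", "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
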