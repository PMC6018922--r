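#' Read a CDS reference from FASTA
#'
#' Builds the per-gene reference table used throughout the pipeline: one row
#' per FASTA entry with its length and GC fraction.  GC is computed as
#' (G + C + S) / (A + C + G + T + S); ambiguity codes other than S (G/C) are
#' excluded from both numerator and denominator so that symmetric ambiguity
#' does not bias the fraction.
#'
#' Family membership is taken from `family_map` when supplied; otherwise a
#' `family=<id>` token in the FASTA description line is honoured, and failing
#' that each gene is its own family.
#'
#' @param path Path to a FASTA file of coding sequences.
#' @param family_map Optional named character vector mapping gene_id to
#'   family_id.
#' @return A `data.frame` with columns `gene_id`, `family_id`, `length_bp`,
#'   `gc_fraction`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 family=famA", "ATGCATGC", ">g2", "GGCCGGCC"), fa)
#' read_reference_fasta(fa)
#' @export
read_reference_fasta <- function(path, family_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path)
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate gene identifiers in FASTA: ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty sequence(s) in FASTA: ",
         paste(ids[Biostrings::width(seqs) == 0L], collapse = ", "))
  }
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T", "S"))
  num <- freq[, "G"] + freq[, "C"] + freq[, "S"]
  den <- rowSums(freq)
  if (any(den == 0)) {
    stop("sequence(s) with no unambiguous A/C/G/T/S bases: ",
         paste(ids[den == 0], collapse = ", "))
  }
  fam <- if (!is.null(family_map)) {
    unname(ifelse(ids %in% names(family_map), family_map[ids], ids))
  } else {
    m <- regmatches(headers, regexpr("family=[^[:space:]]+", headers))
    out <- ids
    has <- grepl("family=", headers)
    out[has] <- sub("^family=", "", m)
    out
  }
  data.frame(gene_id = ids, family_id = fam,
             length_bp = Biostrings::width(seqs),
             gc_fraction = as.numeric(num / den),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive a count table from a SAM/BAM alignment
#'
#' Counts primary alignment records per reference gene.  Secondary and
#' supplementary records are ignored, mirroring an upstream mapper that
#' assigns multi-mapping reads randomly to a single top hit.  Unmapped
#' records contribute to the library size (`total_reads`) only.
#'
#' @param path Path to a SAM or BAM file.
#' @param reference Reference table as returned by [read_reference_fasta()].
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A `count_table` object: list with `sample_id`, `counts` (named
#'   integer vector over all reference genes) and `total_reads`.
#' @export
counts_from_alignment <- function(path, reference, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(names(hdr), reference$gene_id)
  if (length(unknown) > 0L) {
    stop("alignment targets not in reference: ", paste(unknown, collapse = ", "))
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "flag")))[[1]]
  total <- length(rec$flag)
  if (total == 0L) {
    stop("empty library: no records in ", path)
  }
  mapped <- rec$rname[!is.na(rec$rname)]
  tab <- table(factor(as.character(mapped), levels = reference$gene_id))
  count_table(sample_id, stats::setNames(as.integer(tab), reference$gene_id),
              total)
}

#' Construct a count table
#'
#' @param sample_id Sample identifier.
#' @param counts Named non-negative integer vector of read counts per gene.
#' @param total_reads Library size: number of sequencing reads (binomial
#'   trials), which must be at least the largest per-gene count.  Reads may
#'   map nowhere, so `total_reads` can exceed `sum(counts)`.
#' @return A `count_table` object.
#' @export
count_table <- function(sample_id, counts, total_reads) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            !is.null(names(counts)), all(counts >= 0),
            length(total_reads) == 1L, total_reads >= 1)
  if (total_reads < max(counts)) {
    stop("total_reads (", total_reads, ") is smaller than the largest count (",
         max(counts), ")")
  }
  structure(list(sample_id = sample_id,
                 counts = stats::setNames(as.integer(round(counts)), names(counts)),
                 total_reads = as.double(total_reads)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", x$sample_id, "-", length(x$counts), "genes,",
      format(x$total_reads, big.mark = ","), "total reads\n")
  invisible(x)
}

# strict TSV reader: header must contain required columns; every row must
# have as many fields as the header, reported with its line number otherwise
read_tsv_strict <- function(path, required, numeric_cols = character()) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty table: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1] + 1L, " of ", basename(path), ": ",
         nf[bad[1]], " field(s) where ", length(header), " required")
  }
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- header
  if (length(body) == 0L) df <- df[0, , drop = FALSE]
  for (col in intersect(numeric_cols, header)) {
    suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
  }
  df
}

#' Read and write gene reference tables
#'
#' `genes.tsv` columns: `gene_id`, `family_id`, `length_bp`, `gc_fraction`.
#'
#' @param path File path.
#' @return `read_gene_table()` returns the reference `data.frame`.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_strict(path, c("gene_id", "family_id", "length_bp", "gc_fraction"),
                        numeric_cols = c("length_bp", "gc_fraction"))
  df$length_bp <- as.integer(df$length_bp)
  stopifnot(all(df$length_bp >= 1),
            all(df$gc_fraction >= 0 & df$gc_fraction <= 1))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in ", basename(path))
  }
  df
}

#' @param genes Reference table.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "family_id", "length_bp", "gc_fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write count tables
#'
#' `counts.tsv` is long format (`sample_id`, `gene_id`, `count`); library
#' sizes come from the accompanying samples table (`sample_id`,
#' `total_reads`, ...), see [read_sample_table()].
#'
#' @param path Path to `counts.tsv`.
#' @param samples Samples `data.frame` with at least `sample_id` and
#'   `total_reads`.
#' @return `read_count_table()` returns a named list of `count_table`
#'   objects, one per sample.
#' @export
read_count_table <- function(path, samples) {
  df <- read_tsv_strict(path, c("sample_id", "gene_id", "count"),
                        numeric_cols = "count")
  out <- lapply(split(df, df$sample_id), function(d) {
    sid <- d$sample_id[1]
    tr <- samples$total_reads[match(sid, samples$sample_id)]
    if (is.na(tr)) stop("sample ", sid, " absent from samples table")
    count_table(sid, stats::setNames(as.integer(d$count), d$gene_id), tr)
  })
  out[order(names(out))]
}

#' @param tables A `count_table` or list of them.
#' @rdname read_count_table
#' @export
write_count_table <- function(tables, path) {
  if (inherits(tables, "count_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(ct) {
    data.frame(sample_id = ct$sample_id, gene_id = names(ct$counts),
               count = unname(ct$counts), stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples table
#'
#' `samples.tsv` columns: `sample_id`, `total_reads`, `read_pairs`,
#' `read_length_bp`, `genome_size_2cx_gb`, `ploidy`.  Genome size and ploidy
#' may be `NA` (herbarium material often precludes flow cytometry).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_strict(path,
                        c("sample_id", "total_reads", "read_pairs",
                          "read_length_bp", "genome_size_2cx_gb", "ploidy"),
                        numeric_cols = c("total_reads", "read_pairs",
                                         "read_length_bp", "genome_size_2cx_gb",
                                         "ploidy"))
  stopifnot(all(df$total_reads > 0), all(df$read_pairs > 0, na.rm = TRUE),
            all(df$read_length_bp >= 1, na.rm = TRUE),
            all(df$genome_size_2cx_gb > 0, na.rm = TRUE))
  df
}

#' @param samples Samples `data.frame`.
#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SNP read-depth tables
#'
#' `snp.tsv` columns: `gene_id`, `position` (1-based within the reference
#' alignment), `base_a`, `base_b`, `g_depth_a`, `g_depth_b`, `t_depth_a`,
#' `t_depth_b`.  Sites are biallelic by construction; rows where the two
#' bases coincide are rejected.
#'
#' @param path File path.
#' @return A `data.frame` of SNP depth records.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_strict(path,
                        c("gene_id", "position", "base_a", "base_b",
                          "g_depth_a", "g_depth_b", "t_depth_a", "t_depth_b"),
                        numeric_cols = c("position", "g_depth_a", "g_depth_b",
                                         "t_depth_a", "t_depth_b"))
  df$position <- as.integer(df$position)
  for (col in c("g_depth_a", "g_depth_b", "t_depth_a", "t_depth_b")) {
    df[[col]] <- as.integer(df[[col]])
  }
  if (any(df$base_a == df$base_b)) {
    stop("SNP rows with identical variant bases in ", basename(path))
  }
  bad <- !(df$base_a %in% c("A", "C", "G", "T")) |
    !(df$base_b %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("non-ACGT variant base in ", basename(path), " (sites listing more ",
         "than two variants are not supported)")
  }
  stopifnot(all(df$position >= 1),
            all(df$g_depth_a >= 0), all(df$g_depth_b >= 0),
            all(df$t_depth_a >= 0), all(df$t_depth_b >= 0))
  df
}

#' @param snp SNP `data.frame`.
#' @rdname read_snp_table
#' @export
write_snp_table <- function(snp, path) {
  utils::write.table(snp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write transcript-abundance tables
#'
#' `expr.tsv` columns: `accession_id`, `gene_id`, `rpkm` (reads per kilobase
#' per million mapped reads).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_strict(path, c("accession_id", "gene_id", "rpkm"),
                        numeric_cols = "rpkm")
  if (any(df$rpkm < 0)) stop("negative RPKM in ", basename(path))
  df
}

#' @param expr Expression `data.frame`.
#' @rdname read_expression_table
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Newick tree with mandatory branch lengths
#'
#' The Brownian covariance construction needs a length on every edge, so a
#' Newick file without them is rejected outright.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("Newick tree in ", basename(path),
         " lacks branch lengths on some edges; branch lengths are required")
  }
  tree
}
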