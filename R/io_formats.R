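## Readers/writers for every interchange format the pipeline uses. All
## coordinates are 0-based half-open. TSV is the canonical table dialect;
## transcript models are BED12; motifs are JASPAR-style count/probability
## blocks; fragments are BED3 + sample + condition. Every writer/reader pair
## round-trips bit-exactly on the in-memory value.

read_tsv_checked <- function(path, ...) {
  if (!file.exists(path)) stop_gutreg("file not found: ", path)
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "", ...)
}

#' Construct a count matrix container
#'
#' @param counts Integer feature x sample matrix with dimnames.
#' @param samples data.frame of per-sample metadata with a `sample` column
#'   matching `colnames(counts)`.
#' @return Object of class `count_matrix`: list with `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop_gutreg("duplicate or missing feature ids")
  if (!is_count(counts)) stop_gutreg("negative or non-integer counts")
  if (!"sample" %in% names(samples)) stop_gutreg("samples needs a 'sample' column")
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop_gutreg("sample metadata does not match count columns")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("metadata columns:", paste(names(x$samples), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a feature x sample count table
#'
#' The counts TSV has a `feature` column then one column per sample; the
#' companion samples TSV holds per-sample metadata.
#'
#' @param path Counts TSV path.
#' @param samples_path Sample-metadata TSV path.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path, samples_path) {
  tab <- read_tsv_checked(path, colClasses = NA)
  if (names(tab)[1] != "feature") stop_gutreg("first column must be 'feature'")
  feats <- as.character(tab$feature)
  if (anyDuplicated(feats))
    stop_gutreg("duplicate feature ids: ",
                paste(unique(feats[duplicated(feats)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- feats
  bad <- which(m < 0, arr.ind = TRUE)
  if (length(bad))
    stop_gutreg("negative count at line ", bad[1, 1] + 1L)
  samples <- read_tsv_checked(samples_path)
  count_matrix(m, samples)
}

#' @rdname read_counts
#' @param x A `count_matrix`.
#' @export
write_counts <- function(x, path, samples_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(feature = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a taxon table container
#'
#' @param counts Integer taxon x sample matrix.
#' @param samples data.frame with columns `sample`, `individual`, `time`
#'   (one of 0h/1h/2h/4h) and logical `cocultured`; 0h samples must carry
#'   `cocultured = FALSE`.
#' @return Object of class `taxon_table`.
#' @export
taxon_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_gutreg("duplicate or missing taxon ids")
  if (!is_count(counts)) stop_gutreg("negative or non-integer counts")
  need <- c("sample", "individual", "time", "cocultured")
  if (!all(need %in% names(samples)))
    stop_gutreg("sample metadata needs columns: ", paste(need, collapse = ", "))
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop_gutreg("sample metadata does not match count columns")
  if (any(samples$time == "0h" & samples$cocultured))
    stop_gutreg("0h (uncultured) samples cannot be cocultured")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("taxon_table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Read / write a taxon x sample count table
#' @param path,samples_path TSV paths (taxon counts; sample metadata).
#' @return A `taxon_table`.
#' @export
read_taxa <- function(path, samples_path) {
  tab <- read_tsv_checked(path)
  if (names(tab)[1] != "taxon") stop_gutreg("first column must be 'taxon'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$taxon)
  samples <- read_tsv_checked(samples_path)
  samples$cocultured <- as.logical(samples$cocultured)
  taxon_table(m, samples)
}

#' @rdname read_taxa
#' @param x A `taxon_table`.
#' @export
write_taxa <- function(x, path, samples_path) {
  stopifnot(inherits(x, "taxon_table"))
  tab <- data.frame(taxon = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a fragment set
#'
#' ATAC fragment intervals, 0-based half-open, with per-fragment sample and
#' condition labels. Fragment lengths must lie in `[1, 1000]`.
#'
#' @param chrom,start,end,sample,condition Per-fragment vectors.
#' @return data.frame of class `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end, sample, condition) {
  bad <- which(end <= start)
  if (length(bad)) stop_gutreg("fragment end <= start at record ", bad[1])
  bad <- which(end - start > 1000)
  if (length(bad)) stop_gutreg("fragment longer than 1000 bp at record ", bad[1])
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), sample = as.character(sample),
                       condition = as.character(condition),
                       stringsAsFactors = FALSE),
            class = c("fragment_set", "data.frame"))
}

#' Read / write ATAC fragments (BED3 + sample + condition, no header)
#' @param path BED-like TSV path.
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop_gutreg("file not found: ", path)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE, quote = "",
                    col.names = c("chrom", "start", "end", "sample", "condition"))
  fragment_set(tab$chrom, tab$start, tab$end, tab$sample, tab$condition)
}

#' @rdname read_fragments
#' @param x A `fragment_set`.
#' @export
write_fragments <- function(x, path) {
  stopifnot(inherits(x, "fragment_set"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a transcript annotation
#'
#' Each transcript carries its gene, chromosome, strand, TSS (0-based; block
#' start on `+`, block end - 1 on `-`) and sorted non-overlapping exon blocks.
#'
#' @param transcript,gene,chrom,strand,start,end Per-transcript vectors
#'   (`start`/`end`: transcript span, 0-based half-open).
#' @param block_starts,block_sizes Lists of integer vectors (starts relative
#'   to `start`).
#' @return data.frame of class `transcript_annotation` with a computed `tss`.
#' @export
transcript_annotation <- function(transcript, gene, chrom, strand, start, end,
                                  block_starts, block_sizes) {
  if (anyDuplicated(transcript)) stop_gutreg("duplicate transcript ids")
  if (!all(strand %in% c("+", "-"))) stop_gutreg("strand must be + or -")
  for (i in seq_along(block_starts)) {
    bs <- block_starts[[i]]; bz <- block_sizes[[i]]
    if (is.unsorted(bs, strictly = TRUE) || any(bz <= 0) ||
        any(head(bs + bz, -1) > bs[-1]))
      stop_gutreg("exon blocks unsorted or overlapping for ", transcript[i])
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  out <- data.frame(transcript = as.character(transcript),
                    gene = as.character(gene), chrom = as.character(chrom),
                    strand = strand, start = as.integer(start),
                    end = as.integer(end), tss = as.integer(tss),
                    stringsAsFactors = FALSE)
  out$block_starts <- block_starts
  out$block_sizes <- block_sizes
  class(out) <- c("transcript_annotation", "data.frame")
  out
}

#' Read / write transcript models as BED12
#'
#' The BED12 `name` field encodes `transcript|gene`.
#'
#' @param path BED12 path.
#' @return A `transcript_annotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_gutreg("file not found: ", path)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) != 12) stop_gutreg("expected 12 BED columns, got ", ncol(tab))
  ids <- strsplit(tab[[4]], "|", fixed = TRUE)
  split_ints <- function(s) lapply(strsplit(sub(",$", "", s), ","), as.integer)
  transcript_annotation(
    transcript = vapply(ids, `[`, "", 1), gene = vapply(ids, `[`, "", 2),
    chrom = tab[[1]], strand = tab[[6]], start = tab[[2]], end = tab[[3]],
    block_starts = split_ints(tab[[12]]), block_sizes = split_ints(tab[[11]]))
}

#' @rdname read_annotation
#' @param x A `transcript_annotation`.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "transcript_annotation"))
  join <- function(l) vapply(l, function(v) paste(v, collapse = ","), "")
  bed <- data.frame(x$chrom, x$start, x$end, paste0(x$transcript, "|", x$gene),
                    0L, x$strand, x$start, x$end, "0,0,0",
                    lengths(x$block_starts), join(x$block_sizes),
                    join(x$block_starts), stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct a motif model
#'
#' @param id Motif id.
#' @param mat 4 x W probability matrix, rows A, C, G, T; columns must each sum
#'   to 1 within 1e-9. Width W must be at least 4.
#' @param background Background base composition (default uniform).
#' @return Object of class `motif_model`.
#' @export
motif_model <- function(id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop_gutreg("PWM must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 4) stop_gutreg("motif width must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop_gutreg("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop_gutreg("background must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, width = ncol(mat), mat = mat,
                 background = setNames(background, c("A", "C", "G", "T"))),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model", x$id, "width", x$width, "\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' Read / write motifs in JASPAR format
#'
#' Blocks of the form `>ID name` followed by four `A [ ... ]` rows. Counts are
#' converted to probabilities with an additive pseudocount per cell:
#' `p = (c + pseudocount) / (colsum + 4 * pseudocount)`.
#'
#' @param path JASPAR-format file.
#' @param pseudocount Additive pseudocount (default 0).
#' @return Named list of `motif_model`s.
#' @export
read_pwm <- function(path, pseudocount = 0) {
  if (!file.exists(path)) stop_gutreg("file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stop_gutreg("no motif headers ('>') found")
  out <- list()
  for (k in seq_along(starts)) {
    id <- sub("^>\\s*(\\S+).*$", "\\1", lines[starts[k]])
    rows <- lines[starts[k] + 1:4]
    parse_row <- function(ln, want, lineno) {
      base <- sub("^\\s*([ACGT]).*$", "\\1", ln)
      if (base != want)
        stop_gutreg("malformed PWM row at line ", lineno, ": expected ", want)
      s <- sub("^\\s*[ACGT]", "", ln)
      nums <- regmatches(s, gregexpr("[0-9.eE+-]+", s))[[1]]
      as.numeric(nums[nums != "-" & nums != "+"])
    }
    counts <- mapply(parse_row, rows, c("A", "C", "G", "T"),
                     starts[k] + 1:4, SIMPLIFY = FALSE)
    if (length(unique(lengths(counts))) != 1)
      stop_gutreg("ragged PWM block at line ", starts[k])
    cm <- do.call(rbind, counts)
    prob <- sweep(cm + pseudocount, 2, colSums(cm) + 4 * pseudocount, "/")
    out[[id]] <- motif_model(id, prob)
  }
  out
}

#' @rdname read_pwm
#' @param motifs A `motif_model` or list of them.
#' @param digits Digits to print (probabilities are written, not counts).
#' @export
write_pwm <- function(motifs, path, digits = 6) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  con <- file(path, "w"); on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(formatC(m$mat[b, ], digits = digits,
                                       format = "g"), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write genome sequences as FASTA
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_gutreg("file not found: ", path)
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop_gutreg("not a FASTA file: ", path)
  ends <- c(heads[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(heads), function(i)
    toupper(paste(lines[(heads[i] + 1L):ends[i]], collapse = "")), "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads])
  seqs
}

#' @rdname read_genome
#' @param seqs Named character vector of sequences.
#' @param width Line wrap width.
#' @export
write_genome <- function(seqs, path, width = 70) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    idx <- seq(1, nchar(s), by = width)
    writeLines(substring(s, idx, pmin(idx + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write a gene-trait catalog (TSV: gene, trait)
#' @param path TSV path with header `gene	trait`.
#' @return data.frame with columns `gene`, `trait` (one row per membership).
#' @export
read_trait_catalog <- function(path) {
  tab <- read_tsv_checked(path)
  if (!all(c("gene", "trait") %in% names(tab)))
    stop_gutreg("trait catalog needs 'gene' and 'trait' columns")
  tab
}

#' @rdname read_trait_catalog
#' @param x data.frame with `gene` and `trait` columns.
#' @export
write_trait_catalog <- function(x, path) {
  write.table(x[, c("gene", "trait")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a planted-truth record as JSON
#' @param truth A truth record list (from the generators).
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
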