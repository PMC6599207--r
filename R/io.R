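## Readers and writers for the external table / interval formats.
## All intervals are held as GRanges (1-based closed, the Bioconductor
## convention); BED input/output converts to and from 0-based half-open
## coordinates bit-exactly.

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             colClasses = "character", check.names = FALSE,
             strip.white = TRUE)
}

.require_columns <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("format error in %s '%s': missing required column(s) %s",
                 what, path, paste(sQuote(miss), collapse = ", ")), call. = FALSE)
}

.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.format_header(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

.na_blank <- function(x) {
  x[is.na(x) | x %in% c("", "-", "NA", ".")] <- NA_character_
  x
}

.map_diagnosis <- function(x) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  key <- gsub("^_|_$", "", key)
  out <- rep("other", length(key))
  out[key %in% c("de_novo_aml", "de_novo", "denovo_aml")] <- "de_novo_aml"
  out[key %in% c("s_aml", "saml", "secondary_aml") |
        grepl("secondary", key)] <- "s_aml"
  out[key == "remission"] <- "remission"
  factor(out, levels = .diagnosis_levels)
}

#' Read a cohort sample sheet
#'
#' Reads a tab-separated sample sheet with columns \code{sample_id},
#' \code{diagnosis}, \code{cohort}, \code{h3_mutation} and \code{paired_with}.
#' Diagnosis strings are mapped case-insensitively onto
#' \code{de_novo_aml}, \code{s_aml}, \code{remission}; anything else becomes
#' \code{other}. A \code{k27_mutant} flag is derived from the mutation string,
#' and remission samples without a \code{paired_with} link are flagged
#' \code{unpaired}.
#'
#' @param path path to a TSV file (lines starting with '#' are ignored).
#' @return data.frame with columns sample_id, diagnosis (factor), cohort,
#'   h3_mutation, k27_mutant, paired_with, unpaired.
#' @examples
#' sheet <- system.file("extdata", "cohort_samples.tsv",
#'                      package = "oncohistoneScreen")
#' head(readSampleSheet(sheet))
#' @export
readSampleSheet <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "diagnosis", "cohort", "h3_mutation",
                         "paired_with"), "sample sheet", path)
  if (nrow(df) == 0) {
    out <- data.frame(sample_id = character(), diagnosis = factor(levels = .diagnosis_levels),
                      cohort = character(), h3_mutation = character(),
                      k27_mutant = logical(), paired_with = character(),
                      unpaired = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop(sprintf("validation error: duplicate sample_id %s",
                 paste(sQuote(unique(dup)), collapse = ", ")), call. = FALSE)
  h3 <- .na_blank(df$h3_mutation)
  out <- data.frame(
    sample_id = df$sample_id,
    diagnosis = .map_diagnosis(df$diagnosis),
    cohort = df$cohort,
    h3_mutation = h3,
    k27_mutant = !is.na(h3) & grepl("K27", h3),
    paired_with = .na_blank(df$paired_with),
    stringsAsFactors = FALSE
  )
  out$unpaired <- out$diagnosis == "remission" & is.na(out$paired_with)
  out
}

#' Write a cohort sample sheet
#' @param samples data.frame as returned by \code{\link{readSampleSheet}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSampleSheet <- function(samples, path) {
  df <- samples[, c("sample_id", "diagnosis", "cohort", "h3_mutation", "paired_with")]
  .write_tsv(df, path)
}

.parse_callers <- function(x) {
  x <- .na_blank(x)
  ifelse(is.na(x), "", gsub("[;|]", ",", x))
}

.validate_variants <- function(df, assay, path) {
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(.na_blank(df[[col]])) & is.na(v))
    if (length(bad))
      stop(sprintf("format error in '%s': non-numeric %s on data row %d",
                   path, col, bad[1]), call. = FALSE)
    v
  }
  alt_reads <- num("alt_reads")
  depth <- num("depth")
  vaf <- if ("vaf" %in% names(df)) num("vaf") else rep(NA_real_, nrow(df))
  over <- which(!is.na(alt_reads) & !is.na(depth) & alt_reads > depth)
  if (length(over))
    stop(sprintf("validation error in '%s': alt_reads > depth on data row %d",
                 path, over[1]), call. = FALSE)
  ## VAF of record: recomputed from read counts when both are present
  both <- !is.na(alt_reads) & !is.na(depth) & depth > 0
  vaf[both] <- alt_reads[both] / depth[both]
  if (any(is.na(vaf)))
    stop(sprintf("validation error in '%s': neither read counts nor a VAF column for some rows",
                 path), call. = FALSE)
  if (any(vaf < 0 | vaf > 1))
    stop(sprintf("validation error in '%s': VAF outside [0,1]", path), call. = FALSE)
  callers <- if ("callers" %in% names(df)) .parse_callers(df$callers) else
    rep("", nrow(df))
  if (assay == "exome" && any(!nzchar(callers)))
    stop(sprintf("validation error in '%s': exome calls require a non-empty callers field",
                 path), call. = FALSE)
  data.frame(
    sample_id = df$sample_id, gene = df$gene,
    protein_change = df$protein_change, chrom = df$chrom,
    pos = as.integer(num("pos")), ref = df$ref, alt = df$alt,
    alt_reads = alt_reads, depth = depth, vaf = vaf,
    callers = callers, assay = assay, stringsAsFactors = FALSE
  )
}

.read_minimal_vcf <- function(path, assay) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(.validate_variants(
      data.frame(sample_id = character(), gene = character(),
                 protein_change = character(), chrom = character(),
                 pos = character(), ref = character(), alt = character(),
                 alt_reads = character(), depth = character(),
                 callers = character()), assay, path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8))
    stop(sprintf("format error in '%s': minimal VCF requires 8 columns", path),
         call. = FALSE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(sprintf("(?:^|;)%s=([^;]*)", key), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  info <- vapply(fields, `[`, "", 8)
  ad <- strsplit(info_get(info, "AD"), ",", fixed = TRUE)
  alt_reads <- vapply(ad, function(x) x[1], "")
  ref_reads <- suppressWarnings(as.numeric(vapply(ad, function(x) x[2], "")))
  depth <- suppressWarnings(as.numeric(alt_reads)) + ref_reads
  df <- data.frame(
    sample_id = ifelse(is.na(info_get(info, "SAMPLE")),
                       vapply(fields, `[`, "", 3), info_get(info, "SAMPLE")),
    gene = info_get(info, "GENE"),
    protein_change = info_get(info, "AA"),
    chrom = vapply(fields, `[`, "", 1),
    pos = vapply(fields, `[`, "", 2),
    ref = vapply(fields, `[`, "", 4),
    alt = vapply(fields, `[`, "", 5),
    alt_reads = alt_reads,
    depth = as.character(depth),
    callers = info_get(info, "CALLERS"),
    stringsAsFactors = FALSE
  )
  .validate_variants(df, assay, path)
}

#' Read a variant table (TSV or minimal VCF)
#'
#' TSV input requires columns sample_id, gene, protein_change, chrom, pos,
#' ref, alt, alt_reads, depth and optionally vaf and callers. The VAF of
#' record is recomputed as alt_reads/depth whenever both read counts are
#' present; the stated vaf column is used otherwise. A minimal VCF dialect
#' (8 columns, INFO keys \code{AD=alt,ref}, \code{CALLERS=}, \code{SAMPLE=},
#' \code{GENE=}, \code{AA=}) is accepted when the file carries a
#' \code{##fileformat=VCF} line or a \code{.vcf} extension.
#'
#' @param path input path.
#' @param assay "targeted" or "exome"; exome calls must carry caller labels.
#' @return data.frame of validated variant calls, one row per observation.
#' @export
readVariantTable <- function(path, assay = c("targeted", "exome")) {
  assay <- match.arg(assay)
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path, ignore.case = TRUE))
    return(.read_minimal_vcf(path, assay))
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "gene", "protein_change", "chrom", "pos",
                         "ref", "alt"), "variant table", path)
  for (col in c("alt_reads", "depth"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  .validate_variants(df, assay, path)
}

#' Write a variant table as TSV
#' @param calls data.frame of variant calls.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVariantTable <- function(calls, path) {
  .write_tsv(calls, path)
}

#' Read aligned-read intervals from BED6
#'
#' BED6 with the score column carrying the mapping quality. Coordinates are
#' 0-based half-open on disk and are converted to the 1-based closed GRanges
#' convention in memory (a round trip through \code{\link{writeBedReads}} is
#' bit-exact). Chromosomes whose name starts with \code{spikeinPrefix} are
#' tagged \code{species = "spikein"}; all others \code{"target"}.
#'
#' @param path BED6 file (comment and 'track' lines ignored).
#' @param spikeinPrefix chromosome-name prefix marking spike-in reads.
#' @return GRanges with metadata columns \code{name}, \code{mapq},
#'   \code{species}.
#' @export
readBedReads <- function(path, spikeinPrefix = "dmel_") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(GRanges(mapq = integer(), name = character(),
                   species = factor(levels = c("target", "spikein"))))
  }
  fields <- strsplit(lines, "[ \t]+")
  short <- which(lengths(fields) < 6)
  if (length(short))
    stop(sprintf("format error in '%s' line %d: BED6 requires 6 fields",
                 path, lineno[short[1]]), call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  name <- vapply(fields, `[`, "", 4)
  mapq <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  strand <- vapply(fields, `[`, "", 6)
  bad <- which(is.na(start0) | is.na(end0) | is.na(mapq) | start0 < 0)
  if (length(bad))
    stop(sprintf("format error in '%s' line %d: non-numeric or negative coordinates",
                 path, lineno[bad[1]]), call. = FALSE)
  bad <- which(end0 <= start0)
  if (length(bad))
    stop(sprintf("format error in '%s' line %d: end <= start",
                 path, lineno[bad[1]]), call. = FALSE)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("format error in '%s' line %d: strand must be '+' or '-'",
                 path, lineno[bad[1]]), call. = FALSE)
  species <- factor(ifelse(startsWith(chrom, spikeinPrefix), "spikein", "target"),
                    levels = c("target", "spikein"))
  GRanges(chrom, IRanges(start0 + 1, end0), strand = strand,
          name = name, mapq = as.integer(mapq), species = species)
}

#' Write aligned-read intervals as BED6
#' @param reads GRanges as returned by \code{\link{readBedReads}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBedReads <- function(reads, path) {
  nm <- if ("name" %in% names(mcols(reads))) mcols(reads)$name else
    sprintf("r%d", seq_along(reads))
  df <- data.frame(
    chrom = as.character(seqnames(reads)),
    start = format(start(reads) - 1, scientific = FALSE, trim = TRUE),
    end = format(end(reads), scientific = FALSE, trim = TRUE),
    name = nm,
    score = mcols(reads)$mapq,
    strand = as.character(strand(reads))
  )
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build promoter windows around transcription start sites
#'
#' Windows are the 0-based half-open intervals
#' \code{[tss - halfWidth, tss + halfWidth)} clipped at the chromosome start,
#' i.e. 3 kb centered on the TSS by default.
#'
#' @param gene_id character vector, unique per gene.
#' @param chrom chromosome names.
#' @param tss 0-based TSS positions (strand-correct).
#' @param strand "+" or "-".
#' @param halfWidth half window width in bp (default 1500).
#' @return GRanges of windows with metadata gene_id and tss.
#' @export
promoterWindows <- function(gene_id, chrom, tss, strand, halfWidth = 1500) {
  if (anyDuplicated(gene_id))
    stop(sprintf("validation error: duplicate gene_id %s",
                 sQuote(gene_id[duplicated(gene_id)][1])), call. = FALSE)
  tss <- as.numeric(tss)
  start0 <- pmax(0, tss - halfWidth)
  end0 <- tss + halfWidth
  GRanges(chrom, IRanges(start0 + 1, end0), strand = strand,
          gene_id = gene_id, tss = tss)
}

#' Read promoter annotations and build TSS windows
#'
#' Accepts either a TSV with header columns gene_id, chrom, tss, strand
#' (tss already the strand-correct transcription start, 0-based) or a BED6
#' gene file, for which plus-strand TSS = BED start and minus-strand
#' TSS = BED end.
#'
#' @param path input path.
#' @param halfWidth half window width in bp (default 1500 = 3 kb windows).
#' @return GRanges of promoter windows (see \code{\link{promoterWindows}}).
#' @export
readPromoters <- function(path, halfWidth = 1500) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^#", first) & nzchar(first)]
  header <- length(first) && grepl("gene_id", first[1])
  if (header) {
    df <- .read_tsv(path)
    .require_columns(df, c("gene_id", "chrom", "tss", "strand"), "promoter table", path)
    tss <- suppressWarnings(as.numeric(df$tss))
    if (any(is.na(tss)))
      stop(sprintf("format error in '%s': non-numeric tss", path), call. = FALSE)
    return(promoterWindows(df$gene_id, df$chrom, tss, df$strand, halfWidth))
  }
  genes <- readBedReads(path, spikeinPrefix = "\u0001")  # no prefix matches
  tss <- ifelse(as.character(strand(genes)) == "+", start(genes) - 1, end(genes))
  promoterWindows(mcols(genes)$name, as.character(seqnames(genes)), tss,
                  as.character(strand(genes)), halfWidth)
}

#' Write promoter windows as TSV (gene_id, chrom, tss, strand)
#' @param promoters GRanges from \code{\link{readPromoters}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePromoters <- function(promoters, path) {
  df <- data.frame(gene_id = mcols(promoters)$gene_id,
                   chrom = as.character(seqnames(promoters)),
                   tss = format(mcols(promoters)$tss, scientific = FALSE, trim = TRUE),
                   strand = as.character(strand(promoters)))
  .write_tsv(df, path)
}

#' Read a per-replicate expression (RPKM) table
#'
#' TSV with a gene_id column and one column per (condition, replicate) named
#' \code{<condition>_rep<k>}.
#'
#' @param path input path.
#' @return matrix of RPKM values, rownames = gene ids.
#' @export
readExpressionTable <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, "gene_id", "expression table", path)
  m <- as.matrix(vapply(df[setdiff(names(df), "gene_id")],
                        function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, setdiff(names(df), "gene_id")))
  rownames(m) <- df$gene_id
  if (any(is.na(m)))
    stop(sprintf("format error in '%s': non-numeric RPKM values", path), call. = FALSE)
  if (any(m < 0))
    stop(sprintf("validation error in '%s': negative RPKM values", path), call. = FALSE)
  m
}

#' Write an expression matrix as TSV
#' @param rpkm matrix with gene ids as rownames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeExpressionTable <- function(rpkm, path) {
  df <- data.frame(gene_id = rownames(rpkm), rpkm, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read an engraftment table
#'
#' TSV with columns mouse_id, group, percent_engraftment and optionally
#' cells_injected. Percent values must lie in [0, 100].
#'
#' @param path input path.
#' @return data.frame of engraftment records.
#' @export
readEngraftmentTable <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("mouse_id", "group", "percent_engraftment"),
                   "engraftment table", path)
  pct <- suppressWarnings(as.numeric(df$percent_engraftment))
  if (any(is.na(pct)))
    stop(sprintf("format error in '%s': non-numeric percent_engraftment", path),
         call. = FALSE)
  if (any(pct < 0 | pct > 100))
    stop(sprintf("validation error in '%s': percent_engraftment outside [0,100]",
                 path), call. = FALSE)
  out <- data.frame(mouse_id = df$mouse_id, group = df$group,
                    percent_engraftment = pct, stringsAsFactors = FALSE)
  out$cells_injected <- if ("cells_injected" %in% names(df))
    suppressWarnings(as.numeric(df$cells_injected)) else NA_real_
  out
}

#' Write an engraftment table as TSV
#' @param records data.frame of engraftment records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEngraftmentTable <- function(records, path) {
  .write_tsv(records, path)
}
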