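#' Genotype matrix container
#'
#' Samples x SNPs additive dosages (count of ALT/minor alleles, 0/1/2, NA for
#' missing) together with per-SNP coordinates.
#'
#' @param samples Character vector of sample IDs (unique).
#' @param snp_ids Character vector of SNP IDs (unique).
#' @param coords Tibble with columns `snp_id`, `chrom`, `pos` (1-based).
#' @param dosages Numeric matrix, samples x SNPs, values in {0, 1, 2, NA}.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, snp_ids, coords, dosages) {
  samples <- as.character(samples)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(samples)) abort("duplicate sample IDs")
  if (anyDuplicated(snp_ids)) abort("duplicate SNP IDs")
  coords <- as_tibble(coords)
  if (!all(c("snp_id", "chrom", "pos") %in% names(coords))) {
    abort("coords needs columns snp_id, chrom, pos")
  }
  if (nrow(coords) != length(snp_ids)) {
    abort("coords must have one row per SNP")
  }
  dosages <- as.matrix(dosages)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) abort("dosage values must be 0, 1, 2 or NA")
  if (nrow(dosages) != length(samples) || ncol(dosages) != length(snp_ids)) {
    abort("dosage dimensions must match samples x snp_ids")
  }
  dimnames(dosages) <- list(samples, snp_ids)
  structure(
    list(samples = samples, snp_ids = snp_ids,
         coords = coords[match(snp_ids, coords$snp_id), , drop = FALSE],
         dosages = dosages),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
              length(x$samples), length(x$snp_ids),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read genotypes from VCF or a dosage table
#'
#' VCF input uses the GT field of biallelic SNP records: the dosage is the
#' number of ALT alleles; any missing allele gives a missing dosage.
#' Multi-allelic records are dropped with a warning reporting the count.
#' Dosage-table input is a TSV whose first column is the sample ID and whose
#' remaining columns are one SNP each with values 0/1/2/NA; coordinates are
#' then supplied through `snp_coords` (a SNP BED read by [read_bed()]).
#'
#' @param path Input file.
#' @param format `"vcf"`, `"dosage"`, or `"auto"` (by file extension).
#' @param snp_coords For dosage input: tibble with columns `name`, `chrom`,
#'   `start`, `end` (BED, 0-based half-open; a SNP's 1-based position is its
#'   `end`).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           snp_coords = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "vcf") read_genotypes_vcf(path) else {
    read_genotypes_dosage(path, snp_coords)
  }
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("dropped %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) abort("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) abort("duplicate sample IDs in VCF")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- matrix(unname(lut[gt]), nrow = nrow(gt), ncol = ncol(gt))
  snp_ids <- fix$ID
  no_id <- is.na(snp_ids) | snp_ids == "."
  snp_ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  genotype_matrix(
    samples = samples,
    snp_ids = snp_ids,
    coords = tibble(snp_id = snp_ids, chrom = fix$CHROM,
                    pos = as.numeric(fix$POS)),
    dosages = t(dos)
  )
}

read_genotypes_dosage <- function(path, snp_coords = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(tbl) < 2L) abort("dosage table needs a sample column plus >= 1 SNP")
  samples <- tbl[[1]]
  vals <- tbl[, -1, drop = FALSE]
  num <- lapply(vals, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(vals[[j]]) &
                   !(vals[[j]] %in% c("NA", ".")))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric dosage at row %d, column '%s': '%s'",
                    bad[1], names(vals)[j], vals[[j]][bad[1]]))
    }
  }
  dos <- do.call(cbind, num)
  snp_ids <- names(vals)
  coords <- if (is.null(snp_coords)) {
    tibble(snp_id = snp_ids, chrom = NA_character_, pos = NA_real_)
  } else {
    sc <- as_tibble(snp_coords)
    idx <- match(snp_ids, sc$name)
    if (anyNA(idx)) abort("snp_coords is missing some SNPs from the table")
    tibble(snp_id = snp_ids, chrom = sc$chrom[idx], pos = sc$end[idx])
  }
  genotype_matrix(samples, snp_ids, coords, dos)
}

#' Read a BED3+name file
#'
#' @param path BED file (tab-separated, no header): chrom, start, end, name.
#'   Coordinates are 0-based, half-open, and kept that way in memory.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic", comment = "#")
  if (nrow(tbl) == 0L) abort("empty BED file")
  tbl
}

#' Read a phenotype table
#'
#' TSV with a header: first column the sample ID, remaining columns named
#' numeric phenotypes, `NA` for missing.
#'
#' @param path TSV file.
#' @return Tibble: `sample` plus one numeric column per phenotype.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()
  ))
  names(tbl)[1] <- "sample"
  if (ncol(tbl) < 2L) abort("phenotype table needs >= 1 phenotype column")
  if (anyDuplicated(tbl$sample)) abort("duplicate sample IDs in phenotype table")
  tbl
}

#' Assign SNPs to their genomically closest gene
#'
#' A SNP lying inside a gene interval is assigned to it with distance 0; any
#' other SNP goes to the gene on the same chromosome minimising the distance
#' to the nearest interval edge. Equidistant ties break to the gene with the
#' smallest start coordinate, then lexicographically smallest name. SNPs on
#' chromosomes carrying no gene are dropped and counted. With BED's 0-based
#' half-open intervals, a SNP at 1-based position P is inside `[start, end)`
#' iff `start < P <= end`.
#'
#' @param coords Tibble of SNP coordinates: `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param genes Tibble of gene intervals: `chrom`, `start`, `end`, and
#'   `name` (or `gene`); BED convention.
#' @param max_distance Optional cap: SNPs farther than this from every gene
#'   are dropped (default `Inf`, i.e. assign all).
#' @return A `gene_map`: `genes`, `assignment` (tibble `snp_id`, `gene`,
#'   `distance`), and counts of dropped SNPs.
#' @export
assign_snps_to_genes <- function(coords, genes, max_distance = Inf) {
  genes <- as_tibble(genes)
  if ("gene" %in% names(genes) && !"name" %in% names(genes)) {
    genes <- rename(genes, name = gene)
  }
  if (nrow(genes) == 0L) abort("empty gene set")
  coords <- as_tibble(coords)
  out <- vector("list", length(unique(coords$chrom)))
  dropped_chrom <- character(0)
  dropped_far <- character(0)
  i <- 0L
  for (ch in unique(coords$chrom)) {
    snps <- coords[coords$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) {
      dropped_chrom <- c(dropped_chrom, snps$snp_id)
      next
    }
    g <- g[order(g$start, g$name), , drop = FALSE]
    # gap from 1-based position P to BED interval [start, end): 0 for a SNP
    # inside (start < P <= end) or book-ended, else the number of bases
    # between SNP and interval
    d <- pmax(outer(g$start, snps$pos, "-"),
              outer(-g$end, snps$pos, "+"), 0)
    pick <- apply(d, 2, which.min)     # first minimum = smallest start, then name
    dist <- d[cbind(pick, seq_along(pick))]
    keep <- dist <= max_distance
    dropped_far <- c(dropped_far, snps$snp_id[!keep])
    i <- i + 1L
    out[[i]] <- tibble(snp_id = snps$snp_id[keep],
                       gene = g$name[pick][keep],
                       distance = dist[keep])
  }
  assignment <- if (i == 0L) {
    tibble(snp_id = character(0), gene = character(0), distance = numeric(0))
  } else {
    bind_rows(out[seq_len(i)])
  }
  structure(
    list(genes = genes, assignment = assignment,
         dropped_no_gene_chrom = dropped_chrom,
         dropped_beyond_max_distance = dropped_far),
    class = "gene_map"
  )
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("<gene_map> %d SNPs over %d genes (%d dropped)\n",
              nrow(x$assignment), nrow(x$genes),
              length(x$dropped_no_gene_chrom) +
                length(x$dropped_beyond_max_distance)))
  invisible(x)
}

#' Cut a genotype matrix into per-gene dosage blocks
#'
#' Splits columns by the gene assignment, preserving genomic order within
#' each gene, and mean-imputes any missing dosages per SNP (required
#' downstream by the correlation, VIF and CCA steps).
#'
#' @param genotypes A [genotype_matrix()].
#' @param gene_map From [assign_snps_to_genes()].
#' @return Named list of [gene_block()] objects (genes with no assigned SNPs
#'   are absent).
#' @export
make_gene_blocks <- function(genotypes, gene_map) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(gene_map, "gene_map"))
  asg <- gene_map$assignment
  missing_snps <- setdiff(asg$snp_id, genotypes$snp_ids)
  if (length(missing_snps) > 0) {
    abort(paste0("assigned SNP(s) absent from genotype matrix: ",
                 paste(head(missing_snps, 3), collapse = ", ")))
  }
  blocks <- list()
  for (gname in unique(asg$gene)) {
    ids <- asg$snp_id[asg$gene == gname]
    pos <- genotypes$coords$pos[match(ids, genotypes$coords$snp_id)]
    ids <- ids[order(pos)]
    mat <- impute_dosage_means(genotypes$dosages[, ids, drop = FALSE])
    grow <- gene_map$genes[gene_map$genes$name == gname, , drop = FALSE]
    blocks[[gname]] <- gene_block(
      gene = gname, dosages = mat, snp_ids = ids,
      chrom = if (nrow(grow)) grow$chrom[1] else NA_character_,
      start = if (nrow(grow)) grow$start[1] else NA_real_,
      end = if (nrow(grow)) grow$end[1] else NA_real_)
  }
  blocks
}

# per-SNP mean imputation of missing dosages
impute_dosage_means <- function(mat) {
  nas <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(mat, na.rm = TRUE)
    mat[nas] <- mu[nas[, 2]]
  }
  mat
}

## ---- rule table serialization ------------------------------------------

#' Write an association-rule table to TSV
#'
#' Gene and phenotype sets are semicolon-joined; per-item marginal log10
#' p-values are serialized as `name=value` pairs joined by semicolons. The
#' significance threshold used for flagging is echoed as a `#` header line.
#' A legacy linear-scale p-value column is included, floored at the smallest
#' normalised double (reported as 0 below it); the log10 column never clamps.
#'
#' @param rules Rule tibble as produced by the `run_*` pipeline stages:
#'   list-columns `genes`, `phenotypes`, `marginals` plus numeric
#'   `cca_log10_p`, `fisher_log10_p`, logical `significant`.
#' @param path Output file.
#' @param log10_threshold Threshold echoed in the header (default: the
#'   `log10_threshold` attribute of `rules`, if any).
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path,
                        log10_threshold = attr(rules, "log10_threshold")) {
  join <- function(xs) map_chr(xs, paste, collapse = ";")
  join_marg <- function(ms) {
    map_chr(ms, function(m) {
      if (is.null(m) || length(m) == 0) return("")
      paste(sprintf("%s=%.10g", names(m), unname(m)), collapse = ";")
    })
  }
  flat <- tibble(
    genes = join(rules$genes),
    phenotypes = join(rules$phenotypes),
    cca_log10_p = rules$cca_log10_p,
    cca_p = linear_p(rules$cca_log10_p),
    fisher_log10_p = rules$fisher_log10_p %||% rep(NA_real_, nrow(rules)),
    marginals = join_marg(rules$marginals %||%
                            rep(list(numeric(0)), nrow(rules))),
    significant = rules$significant %||% rep(NA, nrow(rules))
  )
  hdr <- sprintf("# log10_threshold=%s",
                 if (is.null(log10_threshold)) "NA" else
                   format(log10_threshold, digits = 12))
  writeLines(hdr, path)
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read an association-rule table written by [write_rules()]
#'
#' @param path TSV file.
#' @return Rule tibble with list-columns `genes`, `phenotypes`, `marginals`;
#'   the threshold header is restored as the `log10_threshold` attribute.
#' @export
read_rules <- function(path) {
  first <- readLines(path, n = 1L)
  thr <- if (grepl("^# log10_threshold=", first)) {
    suppressWarnings(as.numeric(sub("^# log10_threshold=", "", first)))
  } else NA_real_
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    genes = readr::col_character(), phenotypes = readr::col_character(),
    marginals = readr::col_character(), significant = readr::col_logical(),
    .default = readr::col_double()))
  split_set <- function(x) {
    map(x, function(s) if (is.na(s) || s == "") character(0) else
      strsplit(s, ";", fixed = TRUE)[[1]])
  }
  parse_marg <- function(x) {
    map(x, function(s) {
      if (is.na(s) || s == "") return(numeric(0))
      kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      setNames(as.numeric(map_chr(kv, 2)), map_chr(kv, 1))
    })
  }
  out <- tibble(
    genes = split_set(tbl$genes),
    phenotypes = split_set(tbl$phenotypes),
    cca_log10_p = tbl$cca_log10_p,
    cca_p = tbl$cca_p,
    fisher_log10_p = tbl$fisher_log10_p,
    marginals = parse_marg(tbl$marginals),
    significant = tbl$significant
  )
  attr(out, "log10_threshold") <- thr
  out
}

## ---- writers ------------------------------------------------------------

#' Write a genotype matrix as a minimal VCF
#'
#' Biallelic SNP records with a GT field only (`0/0`, `0/1`, `1/1`, `./.`);
#' REF/ALT are placeholder alleles since only dosages are modelled.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  g <- genotypes
  gtmap <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=pleiocca",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  ord <- order(g$coords$chrom, g$coords$pos)
  body <- vapply(ord, function(j) {
    dos <- g$dosages[, j]
    gt <- ifelse(is.na(dos), "./.", gtmap[dos + 1])
    paste(c(g$coords$chrom[j], format(g$coords$pos[j], scientific = FALSE),
            g$snp_ids[j], "A", "C", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write gene intervals as BED4
#'
#' @param genes Tibble with `chrom`, `start`, `end`, `name` (0-based,
#'   half-open).
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  genes <- as_tibble(genes)
  if ("gene" %in% names(genes) && !"name" %in% names(genes)) {
    genes <- rename(genes, name = gene)
  }
  readr::write_tsv(genes[, c("chrom", "start", "end", "name")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a phenotype table as TSV
#'
#' @param phenotypes Tibble: `sample` plus numeric columns; missing written
#'   as `NA`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, na = "NA")
  invisible(path)
}
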