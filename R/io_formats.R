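#' Read a VCF into variant records or a phased haplotype matrix
#'
#' Reads VCF 4.x via \pkg{vcfR}.  Only biallelic single-nucleotide sites are
#' kept: multiallelic or non-SNP records are skipped silently with a logged
#' count.  In `"haplotypes"` mode every retained site must be fully phased
#' (`|` separator); an unphased genotype is a hard error naming the site,
#' while sites with any missing genotype are dropped with a logged count.
#'
#' @param path VCF file.
#' @param popmap `NULL`, a path to a two-column sample/population TSV, or a
#'   data frame with columns `sample` and `pop`.  Required for population
#'   labels in `"haplotypes"` mode; samples without an entry get label
#'   `"ALL"`.
#' @param region optional `"chrom"` or `"chrom:start-end"` filter
#'   (1-based inclusive).
#' @param as `"haplotypes"` (default) returns a [haplotype_matrix()];
#'   `"records"` returns a data frame of variant records (columns `chrom`,
#'   `pos`, `ref`, `alt`, `qual`, `dp`, then one genotype-string column per
#'   sample) suitable for [filter_variants()].
#' @return see `as`.
#' @export
read_vcf <- function(path, popmap = NULL, region = NULL,
                     as = c("haplotypes", "records")) {
  as <- match.arg(as)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))

  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message(n_skip, " multiallelic/non-SNP site(s) skipped")

  keep <- biallelic
  if (!is.null(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0) stop("malformed region: ", region)
    keep <- keep & chrom == m[2]
    if (m[3] != "")
      keep <- keep & pos >= as.integer(m[4]) & pos <= as.integer(m[5])
  }

  rec <- data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                    alt = alt[keep], qual = qual[keep], dp = dp[keep],
                    stringsAsFactors = FALSE)
  gtk <- gt[keep, , drop = FALSE]
  colnames(gtk) <- colnames(gt)
  rec <- cbind(rec, as.data.frame(gtk, stringsAsFactors = FALSE))
  rownames(rec) <- NULL
  if (as == "records") return(rec)
  records_to_haplotypes(rec, popmap = popmap)
}

#' Convert variant records to a phased haplotype matrix
#'
#' @param records data frame as returned by `read_vcf(as = "records")`.
#' @param popmap see [read_vcf()].
#' @return a [haplotype_matrix()].
#' @export
records_to_haplotypes <- function(records, popmap = NULL) {
  if (nrow(records) == 0) stop("no biallelic SNP records to convert")
  if (length(unique(records$chrom)) != 1L)
    stop("records span multiple chromosomes; read one chromosome at a time")
  samples <- setdiff(colnames(records),
                     c("chrom", "pos", "ref", "alt", "qual", "dp"))
  gt <- as.matrix(records[, samples, drop = FALSE])

  missing_site <- apply(gt, 1L, function(z)
    any(is.na(z) | grepl("\\.", z)))
  if (any(missing_site))
    message(sum(missing_site), " site(s) with missing genotypes dropped")
  records <- records[!missing_site, , drop = FALSE]
  gt <- gt[!missing_site, , drop = FALSE]
  if (nrow(records) == 0) stop("no sites left after dropping missing genotypes")

  unphased <- !grepl("^[01]\\|[01]$", gt)
  dim(unphased) <- dim(gt)
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased or invalid genotype '%s' for sample %s at %s:%d",
                 gt[i[1], i[2]], samples[i[2]],
                 records$chrom[i[1]], records$pos[i[1]]))
  }

  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  H <- 2L * length(samples)
  alleles <- matrix(0L, nrow = H, ncol = nrow(records))
  alleles[seq(1L, H, 2L), ] <- t(a1)
  alleles[seq(2L, H, 2L), ] <- t(a2)

  pops <- rep("ALL", length(samples))
  if (!is.null(popmap)) {
    pm <- if (is.character(popmap)) read_popmap(popmap) else popmap
    hit <- match(samples, pm$sample)
    pops[!is.na(hit)] <- pm$pop[hit[!is.na(hit)]]
  }
  haplotype_matrix(chrom = records$chrom[1], positions = records$pos,
                   alleles = alleles, sample_ids = samples,
                   pop_labels = rep(pops, each = 2L),
                   ref = records$ref, alt = records$alt)
}

#' Apply the variant-level quality filter
#'
#' Retains biallelic records with `QUAL >= 20` and site-level `INFO/DP >= 10`
#' (i.e. removes `QUAL < 20` and `DP < 10`), drops records with missing QUAL
#' or DP (counted in the log), and removes monomorphic records when genotype
#' columns are present (only polymorphic SNPs enter the scan).  Idempotent.
#'
#' @param records data frame from `read_vcf(as = "records")`.
#' @param min_qual,min_dp inclusive retention thresholds.
#' @return the filtered records.
#' @export
filter_variants <- function(records, min_qual = 20, min_dp = 10) {
  miss <- is.na(records$qual) | is.na(records$dp)
  if (any(miss))
    message(sum(miss), " record(s) with missing QUAL or DP dropped")
  keep <- !miss & records$qual >= min_qual & records$dp >= min_dp
  out <- records[keep, , drop = FALSE]
  samples <- setdiff(colnames(out),
                     c("chrom", "pos", "ref", "alt", "qual", "dp"))
  if (length(samples) > 0 && nrow(out) > 0) {
    gt <- as.matrix(out[, samples, drop = FALSE])
    alle <- gsub("[|/]", "", gt)
    mono <- apply(alle, 1L, function(z) {
      u <- unique(strsplit(paste(z, collapse = ""), "")[[1]])
      u <- setdiff(u, ".")
      length(u) < 2L
    })
    if (any(mono)) message(sum(mono), " monomorphic record(s) removed")
    out <- out[!mono, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a haplotype matrix as phased VCF 4.2
#'
#' @param hap a [haplotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hap, path) {
  H <- nrow(hap$alleles)
  a1 <- hap$alleles[seq(1L, H, 2L), , drop = FALSE]
  a2 <- hap$alleles[seq(2L, H, 2L), , drop = FALSE]
  gt <- matrix(paste0(t(a1), "|", t(a2)), nrow = ncol(hap$alleles))
  body <- paste(hap$chrom, hap$positions, ".", hap$ref, hap$alt, ".", "PASS",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", hap$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hap$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-population map (two-column TSV)
#' @param path TSV with columns sample, pop; a header row is optional.
#' @return data frame with columns `sample`, `pop`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, col.names = c("sample", "pop"))
  if (nrow(pm) > 0 && identical(tolower(unlist(pm[1, ])),
                                c(sample = "sample", pop = "pop")))
    pm <- pm[-1, , drop = FALSE]
  rownames(pm) <- NULL
  pm
}

#' Read gene models from a GTF file
#'
#' One gene model per `gene_id`, spanning the union of all its features
#' (1-based inclusive coordinates preserved).  A gene whose features fall on
#' more than one chromosome is an error.
#'
#' @param path GTF2.2 file.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by (`chrom`, `start`).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  dat <- !grepl("^#", lines) & nzchar(lines)
  bad <- which(dat & vapply(lines, function(l)
    length(strsplit(l, "\t", fixed = TRUE)[[1]]) < 8L, logical(1)))
  if (length(bad) > 0)
    stop("malformed GTF line ", bad[1], ": fewer than 8 tab-separated fields")
  if (!any(dat))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "gtf")
  gid <- gr$gene_id
  if (is.null(gid) || anyNA(gid))
    stop("GTF features lack gene_id attributes")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  chrom_by_gene <- tapply(chrom, gid, function(x) length(unique(x)))
  if (any(chrom_by_gene > 1L))
    stop("gene_id on multiple chromosomes: ",
         paste(names(chrom_by_gene)[chrom_by_gene > 1L], collapse = ", "))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  ids <- sort(unique(gid))
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(tapply(chrom, gid, function(x) x[1])[ids]),
    start = as.integer(tapply(st, gid, min)[ids]),
    end = as.integer(tapply(en, gid, max)[ids]),
    strand = as.character(tapply(strand, gid,
                                 function(x) if (x[1] %in% c("+", "-")) x[1]
                                 else "+")[ids]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as GTF gene features
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- sprintf("%s\tsweepscanr\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                   genes$chrom, genes$start, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write sweep regions (or any 1-based intervals) as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention and sorts deterministically by (chrom, start).
#'
#' @param regions data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `id` for the BED name column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- order(regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  name <- if ("id" %in% colnames(regions)) regions$id
          else sprintf("region%03d", seq_len(nrow(regions)))
  writeLines(paste(regions$chrom, regions$start - 1L, regions$end, name,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a per-SNP functional annotation table
#'
#' TSV with header columns `chrom`, `pos`, `func_class`; classes must come
#' from the closed set missense / synonymous / intron / intergenic / utr.
#'
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_snp_annotation <- function(path) {
  ann <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "func_class")
  if (!all(req %in% colnames(ann)))
    stop("annotation TSV needs columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(ann$func_class), FUNC_CLASSES)
  if (length(bad) > 0)
    stop("unknown functional class(es): ", paste(bad, collapse = ", "))
  ann$pos <- as.integer(ann$pos)
  ann
}

#' @rdname read_snp_annotation
#' @format NULL
#' @export
FUNC_CLASSES <- c("missense", "synonymous", "intron", "intergenic", "utr")

#' Read a YAML configuration file of pipeline parameters
#'
#' Recognized top-level keys mirror the arguments of [sim_params()],
#' [count_sim_params()] and [run_pipeline()]; unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @param known character vector of accepted keys (`NULL` accepts all).
#' @return named list.
#' @export
read_config <- function(path, known = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(known)) {
    bad <- setdiff(names(cfg), known)
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg
}
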