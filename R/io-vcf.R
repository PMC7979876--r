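#' @importFrom VariantAnnotation readVcf writeVcf info header VCF VCFHeader
#'   fixed alt ref qual filt meta expand "meta<-" "info<-"
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges CharacterList IntegerList NumericList
#'   DataFrameList
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom Biostrings DNAStringSet
NULL

# htslib insists that ##fileformat is the first header line; writeVcf in some
# VariantAnnotation versions prepends ##fileDate before it.
.fixVcfHeaderOrder <- function(path) {
  ln <- readLines(path)
  i <- grep("^##fileformat", ln)
  if (length(i) && i[1] != 1L) writeLines(c(ln[i[1]], ln[-i[1]]), path)
  invisible(path)
}

.vcfBaseHeader <- function(infoDf) {
  hdr <- VCFHeader(samples = character(0))
  meta(hdr) <- DataFrameList(META = DataFrame(Value = "VCFv4.2",
                                              row.names = "fileformat"))
  info(hdr) <- infoDf
  hdr
}

.SNV_INFO_HEADER <- function() DataFrame(
  Number = c("1", "A", "1", "A", "A", "1", "1", "A", "1", "A", "A", "A"),
  Type = c("Integer", "Integer", "Integer", "Integer", "Integer", "Integer",
           "Integer", "Float", "Float", "Float", "Float", "Float"),
  Description = c(
    "Number of alternate alleles at the site",
    "Alternate allele observation count",
    "Reference allele observation count",
    "Alternate observations on the forward strand",
    "Alternate observations on the reverse strand",
    "Reference observations on the forward strand",
    "Reference observations on the reverse strand",
    "Sum of alternate base qualities (phred)",
    "Sum of reference base qualities (phred)",
    "Mean mapping quality of alternate observations",
    "Strand balance probability for the alternate allele (phred)",
    "Reference-read ratio"),
  row.names = c("NUMALT", "AO", "RO", "SAF", "SAR", "SRF", "SRR",
                "QA", "QR", "MQM", "SAP", "AB"))

.expandInfoColumn <- function(v) {
  if (is(v, "List") || is.list(v)) unlist(lapply(v, `[`, 1L)) else v
}

#' Read an annotated small-variant VCF
#'
#' Parses a VCF whose INFO fields carry the observation-count and quality
#' annotations used by the somatic SNV pipeline (AO, RO, SAF, SAR, SRF, SRR,
#' QA, QR, MQM, SAP, AB, NUMALT). Multi-allelic sites are expanded to one
#' record per alternate allele; the site-level allele count is preserved in
#' `numalt` so that site-level filters can still act on it.
#'
#' @param path path to a VCF file.
#' @return A [SmallVariantCalls-class] object, in file order.
#' @export
readSmallVariantVcf <- function(path) {
  vcf <- readVcf(path, genome = "unknown")
  present <- rownames(info(header(vcf)))
  missing <- setdiff(SNV_INFO_FIELDS, present)
  if (length(missing))
    stop("required INFO field(s) missing from ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  ve <- expand(vcf)
  inf <- info(ve)
  qualv <- qual(ve)
  qualv[is.na(qualv)] <- 0
  df <- data.frame(
    chrom = as.character(seqnames(ve)),
    pos = start(ve),
    ref = as.character(ref(ve)),
    alt = as.character(alt(ve)),
    qual = qualv,
    numalt = .expandInfoColumn(inf$NUMALT),
    ao = .expandInfoColumn(inf$AO),
    ro = .expandInfoColumn(inf$RO),
    saf = .expandInfoColumn(inf$SAF),
    sar = .expandInfoColumn(inf$SAR),
    srf = .expandInfoColumn(inf$SRF),
    srr = .expandInfoColumn(inf$SRR),
    qa = .expandInfoColumn(inf$QA),
    qr = .expandInfoColumn(inf$QR),
    mqm = .expandInfoColumn(inf$MQM),
    sap = .expandInfoColumn(inf$SAP),
    ab = .expandInfoColumn(inf$AB),
    stringsAsFactors = FALSE)
  SmallVariantCalls(df)
}

#' Write a SmallVariantCalls object as VCF
#'
#' Records are written in genomic order (chromosome, position), one VCF row
#' per expanded (site, alt) record. Reading the file back with
#' [readSmallVariantVcf()] reproduces the object.
#'
#' @param x a [SmallVariantCalls-class] object.
#' @param path output file path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
writeSmallVariantVcf <- function(x, path) {
  df <- callTable(x)
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$pos, width = nchar(df$ref)))
  fx <- DataFrame(REF = DNAStringSet(df$ref),
                  ALT = CharacterList(as.list(df$alt)),
                  QUAL = df$qual,
                  FILTER = rep(".", nrow(df)))
  asA <- function(v) {
    if (is.integer(v)) IntegerList(as.list(v)) else NumericList(as.list(v))
  }
  inf <- DataFrame(NUMALT = df$numalt, AO = asA(df$ao), RO = df$ro,
                   SAF = asA(df$saf), SAR = asA(df$sar), SRF = df$srf,
                   SRR = df$srr, QA = asA(df$qa), QR = df$qr,
                   MQM = asA(df$mqm), SAP = asA(df$sap), AB = asA(df$ab))
  v <- VCF(rowRanges = gr, fixed = fx, info = inf, collapsed = TRUE)
  metadata(v)$header <- .vcfBaseHeader(.SNV_INFO_HEADER())
  writeVcf(v, path)
  .fixVcfHeaderOrder(path)
  invisible(path)
}

.SV_INFO_HEADER <- function() DataFrame(
  Number = c("1", "1", "1", "1", "0", "0", "1"),
  Type = c("String", "Integer", "String", "Integer", "Flag", "Flag", "Float"),
  Description = c("Type of structural variant",
                  "End position of the variant",
                  "Chromosome of the second breakpoint",
                  "Length of the variant in bases",
                  "Breakpoints resolved at base-pair precision",
                  "Breakpoints imprecise",
                  "Allele fraction reported by the caller"),
  row.names = c("SVTYPE", "END", "CHR2", "SVLEN", "PRECISE", "IMPRECISE",
                "AF"))

#' Read a structural-variant VCF
#'
#' Parses SV records using the SVTYPE/END/CHR2/SVLEN/PRECISE/IMPRECISE/AF
#' INFO conventions. Records with an unrecognised SVTYPE are skipped with a
#' warning and counted in the returned object's skip report. When SVLEN is
#' absent it falls back to `end - start` for intra-chromosomal types and
#' `NA` for translocations. No filtering happens here: decoy-contig and
#' imprecise calls are parsed as-is and handled downstream.
#'
#' @param path path to a VCF file.
#' @return An [SvCallSet-class] object, in file order.
#' @export
readSvVcf <- function(path) {
  vcf <- readVcf(path, genome = "unknown")
  inf <- info(vcf)
  if (is.null(inf$SVTYPE))
    stop("required INFO field(s) missing from ", path, ": SVTYPE",
         call. = FALSE)
  svtype <- as.character(inf$SVTYPE)
  keep <- svtype %in% SV_TYPES
  nskip <- sum(!keep)
  if (nskip)
    warning(nskip, " record(s) with unknown SVTYPE skipped", call. = FALSE)
  chrom <- as.character(seqnames(vcf))[keep]
  startp <- start(vcf)[keep]
  svtype <- svtype[keep]
  endp <- if (!is.null(inf$END)) .expandInfoColumn(inf$END)[keep] else
    rep(NA_integer_, sum(keep))
  chr2 <- if (!is.null(inf$CHR2)) as.character(inf$CHR2)[keep] else
    rep(NA_character_, sum(keep))
  chr2 <- ifelse(is.na(chr2), chrom, chr2)
  endp <- ifelse(is.na(endp), startp, endp)
  svlen <- if (!is.null(inf$SVLEN)) abs(.expandInfoColumn(inf$SVLEN))[keep] else
    rep(NA_real_, sum(keep))
  intra <- svtype %in% INTRA_SV_TYPES
  svlen <- ifelse(is.na(svlen) & intra, endp - startp, svlen)
  if (!is.null(inf$PRECISE)) {
    precise <- inf$PRECISE[keep]
    if (!is.null(inf$IMPRECISE))
      precise <- precise & !inf$IMPRECISE[keep]
  } else if (!is.null(inf$IMPRECISE)) {
    precise <- !inf$IMPRECISE[keep]
  } else {
    precise <- rep(TRUE, sum(keep))
  }
  af <- if (!is.null(inf$AF)) .expandInfoColumn(inf$AF)[keep] else
    rep(NA_real_, sum(keep))
  flt <- filt(vcf)[keep]
  flt[is.na(flt) | flt == "."] <- "PASS"
  SvCallSet(data.frame(
    svtype = svtype, chrom = chrom, start = startp, chr2 = chr2,
    end = as.integer(endp), svlen = svlen, precise = precise, af = af,
    filter_status = flt, source_method = NA_character_,
    truth_label = "unlabelled", stringsAsFactors = FALSE),
    skipped = nskip)
}

#' Write an SvCallSet as VCF
#'
#' Symbolic-allele representation (`<DEL>` etc.) with SVTYPE, END, CHR2,
#' SVLEN, AF and the PRECISE/IMPRECISE flags in INFO. [readSvVcf()] on the
#' output reproduces the coordinate, type, length, precision and allele
#' fraction fields.
#'
#' @param x an [SvCallSet-class] object.
#' @param path output file path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
writeSvVcf <- function(x, path) {
  df <- callTable(x)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$start, width = 1L))
  fx <- DataFrame(REF = DNAStringSet(rep("N", nrow(df))),
                  ALT = CharacterList(as.list(paste0("<", df$svtype, ">"))),
                  QUAL = rep(NA_real_, nrow(df)),
                  FILTER = df$filter_status)
  inf <- DataFrame(SVTYPE = df$svtype, END = as.integer(df$end),
                   CHR2 = df$chr2,
                   SVLEN = as.integer(round(df$svlen)),
                   PRECISE = df$precise, IMPRECISE = !df$precise,
                   AF = df$af)
  v <- VCF(rowRanges = gr, fixed = fx, info = inf, collapsed = TRUE)
  metadata(v)$header <- .vcfBaseHeader(.SV_INFO_HEADER())
  writeVcf(v, path)
  .fixVcfHeaderOrder(path)
  invisible(path)
}
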