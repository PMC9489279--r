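#' Construct a CtTable from a data.frame of qPCR records
#'
#' @param records data.frame with columns strain, species, block, replicate,
#'   role, ct. \code{ct} may be numeric with NA for non-detections, or
#'   character where "NA", "ND" and "" denote non-detections.
#' @param undetectedCt Ct imputed for non-detections when an operation needs
#'   a numeric value (default 40 cycles)
#' @return a [CtTable-class] object
#' @export
ctTable <- function(records, undetectedCt = 40) {
  records <- as.data.frame(records)
  if (is.character(records$ct) || is.factor(records$ct)) {
    ct <- trimws(as.character(records$ct))
    ct[ct %in% c("NA", "ND", "")] <- NA
    records$ct <- suppressWarnings(as.numeric(ct))
    bad <- which(!is.na(ct) & is.na(records$ct))
    if (length(bad))
      stop("non-numeric ct value at row ", bad[1], ": '", ct[bad[1]], "'")
  }
  records$block <- as.integer(records$block)
  records$replicate <- as.integer(records$replicate)
  obj <- .validate_ct_rows(records, undetectedCt)
  exp_blocks <- unique(records$block[records$role == "experimental"])
  b4_blocks <- unique(records$block[records$role == "benchmark4"])
  missing_b4 <- setdiff(exp_blocks, b4_blocks)
  if (length(missing_b4))
    warning("block(s) with experimental records but no benchmark4 records: ",
            paste(missing_b4, collapse = ", "))
  obj
}

# row-level checks that can name the offending row number
.validate_ct_rows <- function(records, undetectedCt) {
  need <- c("strain", "species", "block", "replicate", "role", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(records$role %in% .ct_roles))
  if (length(bad))
    stop("unknown role '", records$role[bad[1]], "' at row ", bad[1])
  bad <- which(!is.na(records$ct) & (records$ct <= 0 | records$ct > 40))
  if (length(bad))
    stop("ct value ", records$ct[bad[1]], " outside (0, 40] at row ", bad[1])
  key <- paste(records$strain, records$block, records$replicate, records$role)
  bad <- which(duplicated(key))
  if (length(bad))
    stop("duplicate (strain, block, replicate, role) at row ", bad[1])
  new("CtTable", records = records[, need], undetectedCt = undetectedCt)
}

#' Read a Ct table from a delimited text file
#'
#' Comma- or tab-delimited (auto-detected from the header line), UTF-8, with
#' header columns strain, species, block, replicate, role, ct. The strings
#' "NA", "ND" and an empty field denote undetected virus.
#'
#' @inheritParams ctTable
#' @param path file path
#' @return a [CtTable-class]
#' @export
readCtTable <- function(path, undetectedCt = 40) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  records <- utils::read.table(path, sep = sep, header = TRUE,
                               colClasses = "character",
                               na.strings = character(),
                               fileEncoding = "UTF-8")
  ctTable(records, undetectedCt = undetectedCt)
}

#' Write a Ct table as TSV
#'
#' @param x a [CtTable-class]
#' @param path output file; non-detections are written as "ND"
#' @export
writeCtTable <- function(x, path) {
  rec <- ctRecords(x)
  rec$ct <- ifelse(is.na(rec$ct), "ND", format(rec$ct, trim = TRUE))
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Within-strain standard deviation of replicate Ct values
#'
#' For each experimental strain with at least two replicates, the sample
#' variance of its replicate Cts is computed (pooled across blocks, with
#' non-detections imputed to \code{undetectedCt(x)}); the variances are then
#' averaged over strains and the square root taken. This is the
#' within-strain spread used to pad the benchmark-derived susceptibility
#' threshold. Controls and benchmarks are excluded.
#'
#' @param x a [CtTable-class]
#' @return sigma_w, the square root of the mean per-strain variance
#' @examples
#' # strains with replicate Cts {30,32} and {40,40}: variances 2 and 0,
#' # mean 1, sigma_w = 1
#' @export
withinStrainSd <- function(x) {
  rec <- ctRecords(x)
  rec <- rec[rec$role == "experimental", ]
  if (!nrow(rec)) stop("no experimental records")
  ct <- ifelse(is.na(rec$ct), undetectedCt(x), rec$ct)
  n_imputed <- sum(is.na(rec$ct))
  if (n_imputed)
    message(n_imputed, " undetected experimental Ct(s) imputed to ",
            undetectedCt(x))
  v <- tapply(ct, rec$strain, function(z)
    if (length(z) >= 2) stats::var(z) else NA_real_)
  dropped <- names(v)[is.na(v)]
  if (length(dropped))
    message("strain(s) with <2 replicates excluded from sigma_w: ",
            paste(dropped, collapse = ", "))
  v <- v[!is.na(v)]
  if (!length(v)) stop("no strain has >= 2 experimental replicates")
  sqrt(mean(v))
}

#' Derive the susceptibility Ct threshold from benchmark samples
#'
#' With \code{benchmark = 4} (default): the threshold is one within-strain
#' standard deviation \emph{more virus} than the most virus seen in any
#' benchmark-4 well, i.e. \code{tau = min(detected benchmark-4 Ct) - sigmaW}
#' (lower Ct means more virus). Benchmark 4 quantifies exposure virus
#' remaining after washing, so samples below \code{tau} carry clearly more
#' virus than carry-over can explain. With \code{benchmark = 5} the highly
#' conservative alternative is used: \code{tau = min(detected benchmark-5
#' Ct)}, the most virus possible without any replication.
#'
#' @param x a [CtTable-class]
#' @param sigmaW within-strain sd from [withinStrainSd()] (ignored for
#'   \code{benchmark = 5})
#' @param benchmark 4 (default) or 5
#' @return list with elements \code{benchmarkMaxVirusCt} (minimum detected
#'   benchmark Ct), \code{sigmaW}, \code{threshold} and \code{benchmark}
#' @examples
#' # benchmark-4 minimum detected Ct 33.6 and sigma_w 4.1 give tau = 29.5
#' @export
deriveThreshold <- function(x, sigmaW, benchmark = 4) {
  stopifnot(benchmark %in% c(4, 5))
  role <- paste0("benchmark", benchmark)
  rec <- ctRecords(x)
  ct <- rec$ct[rec$role == role & !is.na(rec$ct)]
  if (!length(ct))
    stop("no detected ", role, " record: cannot derive a threshold")
  mostVirus <- min(ct)
  if (benchmark == 5) sigmaW <- 0
  if (!is.finite(sigmaW) || sigmaW < 0) stop("sigmaW must be finite and >= 0")
  list(benchmarkMaxVirusCt = mostVirus, sigmaW = sigmaW,
       threshold = mostVirus - sigmaW, benchmark = benchmark)
}

#' Call susceptibility per strain from a Ct threshold
#'
#' A strain is susceptible if at least one experimental replicate population
#' had more virus than the threshold, i.e. a detected Ct strictly below
#' \code{tau}. Equality does not count, and non-detections (imputed to the
#' table's \code{undetectedCt}) can never fall below any \code{tau} below
#' that value. Controls and benchmarks are excluded.
#'
#' @param x a [CtTable-class]
#' @param threshold numeric \code{tau}, or the list from [deriveThreshold()]
#' @return data.frame with columns strain, species, n_replicates,
#'   n_infected, susceptible
#' @export
callSusceptibility <- function(x, threshold) {
  if (is.list(threshold)) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  rec <- ctRecords(x)
  rec <- rec[rec$role == "experimental", ]
  if (!nrow(rec))
    return(data.frame(strain = character(), species = character(),
                      n_replicates = integer(), n_infected = integer(),
                      susceptible = logical()))
  ct <- ifelse(is.na(rec$ct), undetectedCt(x), rec$ct)
  infected <- ct < threshold
  strains <- unique(rec$strain)
  out <- do.call(rbind, lapply(strains, function(s) {
    i <- rec$strain == s
    data.frame(strain = s, species = rec$species[i][1],
               n_replicates = sum(i), n_infected = sum(infected[i]))
  }))
  out$susceptible <- out$n_infected >= 1
  rownames(out) <- NULL
  out
}

#' Summarize controls and benchmarks
#'
#' Mean and standard deviation of detected Ct values per non-experimental
#' role, with the number of detected wells. Roles absent from the table are
#' omitted with a warning; a role observed once has an undefined sd (NA).
#'
#' @param x a [CtTable-class]
#' @return data.frame with columns role, n_detected, mean_ct, sd_ct
#' @export
summarizeBenchmarks <- function(x) {
  rec <- ctRecords(x)
  roles <- setdiff(.ct_roles, "experimental")
  absent <- setdiff(roles, unique(rec$role))
  if (length(absent))
    warning("role(s) absent from table: ", paste(absent, collapse = ", "))
  roles <- intersect(roles, unique(rec$role))
  out <- do.call(rbind, lapply(roles, function(r) {
    ct <- rec$ct[rec$role == r & !is.na(rec$ct)]
    data.frame(role = r, n_detected = length(ct),
               mean_ct = if (length(ct)) mean(ct) else NA_real_,
               sd_ct = if (length(ct) >= 2) stats::sd(ct) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Score a serial-passage trajectory
#'
#' Ordinal 0-3 summary of viral persistence through passaging of an exposed
#' population: 0 if virus was never detected in the primary exposure
#' population (passage 0); 1 if detected at passage 0 but not in the first
#' passage population; 2 if detected in the first passage population but
#' undetectable on or before passage 5; 3 if still detectable at passage 5.
#'
#' Lines whose passaging stopped at the first non-detection are accepted as
#' short trajectories ending in \code{FALSE} and are treated as undetected
#' thereafter. A trajectory that is detected at its last recorded passage
#' but does not reach passage 5 is ambiguous (score 2 vs 3) and raises a
#' "truncated trajectory" error.
#'
#' @param detections logical vector of per-passage detections, passage 0
#'   first, at most 6 entries (passages 0-5)
#' @return integer score in 0:3
#' @examples
#' scoreTransmission(c(FALSE))                                   # 0
#' scoreTransmission(c(TRUE, FALSE))                             # 1
#' scoreTransmission(c(TRUE, TRUE, TRUE, FALSE))                 # 2
#' scoreTransmission(rep(TRUE, 6))                               # 3
#' @export
scoreTransmission <- function(detections) {
  detections <- as.logical(detections)
  if (!length(detections) || anyNA(detections))
    stop("detections must be a non-empty logical vector without NA")
  if (length(detections) > 6)
    stop("at most 6 passages (0-5) are supported")
  if (!detections[1]) return(0L)
  if (length(detections) < 6) {
    if (detections[length(detections)])
      stop("truncated trajectory: detected at last recorded passage ",
           length(detections) - 1,
           " but passage 5 status unknown (cannot distinguish score 2 from 3)")
    detections <- c(detections, rep(FALSE, 6 - length(detections)))
  }
  if (!detections[2]) return(1L)
  if (detections[6]) 3L else 2L
}

#' Read passage trajectories from a delimited file
#'
#' Long format with header columns line_id, strain, passage (0-5), detected
#' (0/1 or TRUE/FALSE) and passage0_ct ("ND"/"NA"/empty for undetected).
#' Comma- or tab-delimited, auto-detected.
#'
#' @param path file path
#' @return data.frame in long format, passages ordered within line
#' @export
readTrajectories <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character",
                          na.strings = character(), fileEncoding = "UTF-8")
  need <- c("line_id", "strain", "passage", "detected", "passage0_ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$passage <- as.integer(df$passage)
  df$detected <- as.logical(as.integer(df$detected))
  ct <- trimws(df$passage0_ct)
  ct[ct %in% c("NA", "ND", "")] <- NA
  df$passage0_ct <- suppressWarnings(as.numeric(ct))
  df[order(df$line_id, df$passage), ]
}

#' Score all trajectories in a long-format table
#'
#' @param trajectories data.frame as returned by [readTrajectories()] (or
#'   built in code) with columns line_id, strain, passage, detected,
#'   passage0_ct
#' @return data.frame with one row per line: line_id, strain, score,
#'   passage0_ct
#' @export
scoreTransmissionTable <- function(trajectories) {
  lines <- unique(trajectories$line_id)
  out <- do.call(rbind, lapply(lines, function(l) {
    tr <- trajectories[trajectories$line_id == l, ]
    tr <- tr[order(tr$passage), ]
    if (!identical(as.integer(tr$passage), seq_len(nrow(tr)) - 1L))
      stop("line ", l, ": passages must be consecutive starting at 0")
    data.frame(line_id = l, strain = tr$strain[1],
               score = scoreTransmission(tr$detected),
               passage0_ct = tr$passage0_ct[1])
  }))
  rownames(out) <- NULL
  out
}
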