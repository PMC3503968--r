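#' Write a split network as a SplitsTree-compatible NEXUS file
#'
#' Emits a `TAXA` block and a `SPLITS` block (cycle plus weighted splits;
#' with `confidences=yes` when bootstrap supports are present).  Split rows
#' list the weight, the confidence when present, then the taxon indices of
#' one side, comma-terminated — the dialect split-network viewers accept.
#'
#' @param net a [SplitNetwork-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readSplitsNexus()]
#' @export
writeSplitsNexus <- function(net, path) {
  stopifnot(is(net, "SplitNetwork"))
  hasConf <- length(net@supports) > 0 && !all(is.na(net@supports))
  lines <- c(
    "#NEXUS",
    "",
    "BEGIN TAXA;",
    sprintf("DIMENSIONS NTAX=%d;", length(net@taxa)),
    "TAXLABELS",
    sprintf("  '%s'", net@taxa),
    ";",
    "END;",
    "",
    "BEGIN SPLITS;",
    sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", length(net@taxa),
            length(net@splits)),
    sprintf("FORMAT LABELS=NO WEIGHTS=YES CONFIDENCES=%s;",
            if (hasConf) "YES" else "NO"),
    sprintf("CYCLE %s;", paste(net@cycle, collapse = " ")),
    "MATRIX")
  rows <- vapply(seq_along(net@splits), function(k) {
    side <- paste(net@splits[[k]], collapse = " ")
    if (hasConf)
      sprintf("%.10g %.10g %s,", net@weights[k], net@supports[k], side)
    else
      sprintf("%.10g %s,", net@weights[k], side)
  }, character(1))
  lines <- c(lines, rows, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a NEXUS splits file written by writeSplitsNexus()
#'
#' @param path file path.
#' @return a [SplitNetwork-class].
#' @export
readSplitsNexus <- function(path) {
  lines <- trimws(readLines(path))
  if (!length(lines) || toupper(lines[1]) != "#NEXUS")
    stopf("'%s' is not a NEXUS file", path)
  up <- toupper(lines)
  grab <- function(block) {
    beg <- grep(paste0("^BEGIN ", block, ";"), up)
    if (!length(beg)) stopf("missing %s block", block)
    end <- grep("^END;", up)
    end <- end[end > beg[1]][1]
    lines[(beg[1] + 1L):(end - 1L)]
  }
  tx <- grab("TAXA")
  labStart <- grep("^TAXLABELS", toupper(tx)) + 1L
  labEnd <- grep("^;", tx)
  labEnd <- labEnd[labEnd >= labStart][1] - 1L
  taxa <- gsub("^'|'$", "", tx[labStart:labEnd])

  sp <- grab("SPLITS")
  upsp <- toupper(sp)
  hasConf <- any(grepl("CONFIDENCES=YES", upsp))
  cyc <- sp[grep("^CYCLE", upsp)]
  cycle <- as.integer(strsplit(gsub("^CYCLE\\s+|;$", "", cyc), "\\s+")[[1]])
  mStart <- grep("^MATRIX", upsp) + 1L
  mEnd <- grep("^;", sp)
  mEnd <- mEnd[mEnd >= mStart]
  rows <- if (length(mEnd) && mEnd[1] > mStart) sp[mStart:(mEnd[1] - 1L)]
          else character(0)
  splits <- list(); weights <- numeric(0); supports <- numeric(0)
  for (r in rows) {
    f <- strsplit(gsub(",$", "", r), "\\s+")[[1]]
    weights <- c(weights, as.numeric(f[1]))
    if (hasConf) {
      supports <- c(supports, as.numeric(f[2]))
      splits[[length(splits) + 1L]] <- as.integer(f[-(1:2)])
    } else {
      supports <- c(supports, NA_real_)
      splits[[length(splits) + 1L]] <- as.integer(f[-1])
    }
  }
  new("SplitNetwork", taxa = taxa, cycle = cycle, splits = splits,
      weights = weights, supports = supports)
}
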