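#' Binned chromatin-contact maps
#'
#' A `contact_map` holds symmetric interaction counts between fixed-size
#' genome bins for one restriction-enzyme experiment (e.g. a HindIII- or
#' NcoI-map), already normalised upstream; counts may therefore be
#' fractional. Each unordered bin pair is stored once in canonical
#' orientation (lower-sorted bin first); pairs not stored have count 0.
#'
#' @param entries Data frame with columns `chromA`, `binA`, `chromB`, `binB`,
#'   `count`. Both orientations of a pair may be supplied as long as their
#'   counts agree.
#' @param enzyme_label Name of the enzyme map.
#' @param bin_size Bin size in bp shared by all bins.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(entries = NULL, enzyme_label = "map", bin_size = 1e6) {
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- data.frame(
      chromA = character(), binA = integer(),
      chromB = character(), binB = integer(), count = numeric(),
      stringsAsFactors = FALSE
    )
  }
  need <- c("chromA", "binA", "chromB", "binB", "count")
  if (!all(need %in% names(entries))) {
    input_error(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  }
  entries <- entries[need]
  entries$chromA <- as.character(entries$chromA)
  entries$chromB <- as.character(entries$chromB)
  if (any(entries$count < 0)) input_error("interaction counts must be >= 0")
  if (any(entries$binA < 0) || any(entries$binB < 0)) input_error("bin indices must be >= 0")

  # canonical orientation: (chrom, index) of the lower-sorted bin first
  swap <- entries$chromA > entries$chromB |
    (entries$chromA == entries$chromB & entries$binA > entries$binB)
  if (any(swap)) {
    tmp <- entries[swap, c("chromB", "binB", "chromA", "binA")]
    entries[swap, c("chromA", "binA", "chromB", "binB")] <- tmp
  }
  key <- pair_key(entries)
  if (anyDuplicated(key)) {
    agg <- tapply(entries$count, key, function(x) length(unique(x)))
    if (any(agg > 1)) {
      bad <- names(agg)[agg > 1][1]
      consistency_error(sprintf(
        "conflicting counts for bin pair %s (map stored asymmetrically)", bad
      ))
    }
    entries <- entries[!duplicated(key), ]
  }
  entries <- entries[order(entries$chromA, entries$binA, entries$chromB, entries$binB), ]
  rownames(entries) <- NULL
  structure(
    list(enzyme_label = enzyme_label, bin_size = bin_size, entries = entries),
    class = "contact_map"
  )
}

pair_key <- function(e) paste(e$chromA, e$binA, e$chromB, e$binB, sep = "|")

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact_map '%s': %d bin pair(s) at bin size %s bp\n",
    x$enzyme_label, nrow(x$entries), format(x$bin_size, scientific = FALSE)
  ))
  invisible(x)
}

#' Look up the interaction count of a bin pair
#'
#' @param map A `contact_map`.
#' @param chromA,binA,chromB,binB The two bins, in either order.
#' @return The stored count, or 0 for pairs not stored.
#' @export
contact_count <- function(map, chromA, binA, chromB, binB) {
  e <- data.frame(
    chromA = as.character(chromA), binA = binA,
    chromB = as.character(chromB), binB = binB, count = 0,
    stringsAsFactors = FALSE
  )
  swap <- e$chromA > e$chromB | (e$chromA == e$chromB & e$binA > e$binB)
  if (any(swap)) {
    tmp <- e[swap, c("chromB", "binB", "chromA", "binA")]
    e[swap, c("chromA", "binA", "chromB", "binB")] <- tmp
  }
  hit <- match(pair_key(e), pair_key(map$entries))
  ifelse(is.na(hit), 0, map$entries$count[hit])
}

#' Read a contact map from the tab-separated bin-pair dialect
#'
#' The dialect has `#`-prefixed `key=value` metadata lines (`enzyme_label`,
#' `bin_size`), a header `chromA binA chromB binB count`, and one unordered
#' bin pair per row. If both orientations of a pair occur with different
#' counts the file is rejected as inconsistent.
#'
#' @param path Path to the TSV file.
#' @param enzyme_label Optional override for the enzyme label; defaults to the
#'   file's metadata, then to the file name.
#' @return A `contact_map`.
#' @export
read_contact_map <- function(path, enzyme_label = NULL) {
  if (!file.exists(path)) input_error(sprintf("contact map not found: %s", path))
  lines <- readLines(path)
  meta <- list()
  is_comment <- grepl("^#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", cl))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  header_cols <- c("chromA", "binA", "chromB", "binB", "count")
  if (length(body_idx) == 0) {
    # header-only / empty file -> empty map
    return(contact_map(NULL,
      enzyme_label = enzyme_label %||% meta$enzyme_label %||% basename(path),
      bin_size = as.numeric(meta$bin_size %||% 1e6)
    ))
  }
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, header_cols)) {
    parse_error(sprintf(
      "%s line %d: expected header '%s'", path, body_idx[1],
      paste(header_cols, collapse = "\t")
    ))
  }
  rows <- lapply(body_idx[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5) parse_error(sprintf("%s line %d: expected 5 fields, got %d", path, i, length(f)))
    binA <- suppressWarnings(as.integer(f[2]))
    binB <- suppressWarnings(as.integer(f[4]))
    count <- suppressWarnings(as.numeric(f[5]))
    if (is.na(binA) || is.na(binB)) parse_error(sprintf("%s line %d: non-integer bin index", path, i))
    if (is.na(count)) parse_error(sprintf("%s line %d: non-numeric count", path, i))
    if (count < 0) parse_error(sprintf("%s line %d: negative count", path, i))
    data.frame(
      chromA = f[1], binA = binA, chromB = f[3], binB = binB, count = count,
      stringsAsFactors = FALSE
    )
  })
  entries <- do.call(rbind, rows)
  contact_map(entries,
    enzyme_label = enzyme_label %||% meta$enzyme_label %||% basename(path),
    bin_size = as.numeric(meta$bin_size %||% 1e6)
  )
}

#' Write a contact map in the tab-separated bin-pair dialect
#'
#' Rows are written in canonical orientation and sorted order so identical
#' maps serialise byte-identically; re-reading reproduces the map exactly.
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  e <- map$entries
  lines <- c(
    sprintf("# enzyme_label=%s", map$enzyme_label),
    sprintf("# bin_size=%s", format(map$bin_size, scientific = FALSE)),
    "chromA\tbinA\tchromB\tbinB\tcount",
    if (nrow(e)) {
      sprintf("%s\t%d\t%s\t%d\t%s", e$chromA, e$binA, e$chromB, e$binB,
              sprintf("%.17g", e$count))
    }
  )
  tryCatch(writeLines(lines, path),
           error = function(err) input_error(sprintf("cannot write %s: %s", path, conditionMessage(err))))
  invisible(path)
}

#' Rank the interaction partners of an anchor bin
#'
#' Partners are the bins that share a stored pair with the anchor, sorted by
#' interaction count descending; ties are broken by chromosome name
#' (lexicographic) then bin index ascending, so rankings are deterministic.
#' The anchor never appears as its own partner.
#'
#' @param map A `contact_map`.
#' @param anchor One-row bin data frame (see [bin_of_position()]); its
#'   `bin_size` must match the map's.
#' @param scope `"intra"` keeps partners on the anchor's chromosome,
#'   `"inter"` keeps other chromosomes, `"all"` keeps both.
#' @param top_k Maximum number of partners to return (`Inf` = unlimited).
#' @return A data frame of class `partner_ranking` with columns `chrom`,
#'   `index`, `count`, ordered by rank; attributes `anchor`, `scope`,
#'   `enzyme_label`.
#' @export
rank_partners <- function(map, anchor, scope = c("intra", "inter", "all"), top_k = Inf) {
  scope <- match.arg(scope)
  if (!isTRUE(all.equal(anchor$bin_size, map$bin_size))) {
    rs_stop(
      sprintf("anchor bin size %s does not match map bin size %s",
              format(anchor$bin_size), format(map$bin_size)),
      c("regscout_incompatible_resolution", "regscout_input_error")
    )
  }
  e <- map$entries
  a_first <- e$chromA == anchor$chrom & e$binA == anchor$index
  a_second <- e$chromB == anchor$chrom & e$binB == anchor$index
  partners <- rbind(
    data.frame(chrom = e$chromB[a_first], index = e$binB[a_first],
               count = e$count[a_first], stringsAsFactors = FALSE),
    data.frame(chrom = e$chromA[a_second], index = e$binA[a_second],
               count = e$count[a_second], stringsAsFactors = FALSE)
  )
  partners <- partners[!(partners$chrom == anchor$chrom & partners$index == anchor$index), ]
  partners <- switch(scope,
    intra = partners[partners$chrom == anchor$chrom, ],
    inter = partners[partners$chrom != anchor$chrom, ],
    all = partners
  )
  partners <- partners[order(-partners$count, partners$chrom, partners$index), ]
  if (is.finite(top_k)) partners <- utils::head(partners, top_k)
  rownames(partners) <- NULL
  structure(partners,
    anchor = anchor[c("chrom", "index", "bin_size")],
    scope = scope,
    enzyme_label = map$enzyme_label,
    class = c("partner_ranking", "data.frame")
  )
}

#' Consensus partners across several enzyme maps
#'
#' The published worked example reports each enzyme map's counts separately;
#' this is the explicit combiner: a bin is ordered first by the number of
#' maps in whose top-`k` it appears, then by its best (smallest) rank in any
#' map, then by chromosome name and bin index. A bin present in every map's
#' top-`k` therefore precedes one supported by a single map.
#'
#' @param rankings List of `partner_ranking` objects sharing anchor and scope.
#' @param k Depth of each map's top list considered.
#' @return A data frame with columns `chrom`, `index`, `n_maps`, `best_rank`.
#' @export
consensus_top_partners <- function(rankings, k) {
  if (length(rankings) == 0 || k < 1) {
    return(data.frame(chrom = character(), index = integer(),
                      n_maps = integer(), best_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  anchors <- lapply(rankings, attr, "anchor")
  same <- vapply(anchors, function(a) {
    identical(a$chrom, anchors[[1]]$chrom) && identical(a$index, anchors[[1]]$index)
  }, logical(1))
  if (!all(same)) input_error("rankings have mixed anchors")
  if (length(unique(vapply(rankings, attr, "", "scope"))) > 1) {
    input_error("rankings have mixed scopes")
  }
  tops <- lapply(rankings, function(r) utils::head(as.data.frame(r), k))
  bins <- unique(do.call(rbind, lapply(tops, function(t) t[c("chrom", "index")])))
  if (nrow(bins) == 0) {
    return(data.frame(chrom = character(), index = integer(),
                      n_maps = integer(), best_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  stats_ <- t(vapply(seq_len(nrow(bins)), function(i) {
    ranks <- vapply(tops, function(t) {
      hit <- which(t$chrom == bins$chrom[i] & t$index == bins$index[i])
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    c(n_maps = sum(!is.na(ranks)), best_rank = min(ranks, na.rm = TRUE))
  }, c(n_maps = 0L, best_rank = 0L)))
  out <- cbind(bins, as.data.frame(stats_))
  out <- out[order(-out$n_maps, out$best_rank, out$chrom, out$index), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
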