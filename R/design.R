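# Gate-based scanning of target backbones and mutation/insertion planning.

GATE_OFFSET <- c(x1 = 0L, C1 = 1L, x2 = 2L, x3 = 3L, C2 = 4L, H = 5L)

#' Scan a dihedral table against a gate set
#'
#' Slides a 6-residue window (`x1 C1 x2 x3 C2 H`) along every chain and
#' tests each gated position/angle for strict containment in its interval.
#' Windows with any undefined required angle fail closed with reason
#' `"undefined:<position>.<angle>"`.  The histidine position is checked for
#' existence only (the window must have six residues); it carries no torsion
#' gate in the published set.
#'
#' @param dihedrals a `dihedral_table` for one target structure.
#' @param gates a `gate_set`, e.g. [published_gates()].
#' @return data frame of class `candidate_sites`: one row per possible
#'   window start (`chain`, `start_index`, `start_auth`), a logical column
#'   `ok_<position>_<angle>` per gated check (NA when the angle is
#'   undefined), the overall `pass` flag and a `reason` string listing the
#'   failed checks (empty for passing windows).
#' @export
gate_scan <- function(dihedrals, gates) {
  gg <- gates[gates$gated, , drop = FALSE]
  out <- list()
  for (ch in unique(dihedrals$chain)) {
    d <- dihedrals[dihedrals$chain == ch, , drop = FALSE]
    d <- d[order(d$res_index), , drop = FALSE]
    n <- nrow(d)
    if (n < 6L) next
    starts <- seq_len(n - 5L)
    checks <- matrix(NA, nrow = length(starts), ncol = nrow(gg))
    colnames(checks) <- paste0("ok_", gg$position, "_", gg$angle)
    for (j in seq_len(nrow(gg))) {
      off <- GATE_OFFSET[[gg$position[j]]]
      v <- d[[gg$angle[j]]][starts + off]
      checks[, j] <- ifelse(is.na(v), NA, v > gg$min[j] & v < gg$max[j])
    }
    pass <- apply(checks, 1L, function(r) all(!is.na(r)) && all(r))
    reason <- vapply(seq_along(starts), function(i) {
      r <- checks[i, ]
      lab <- paste0(gg$position, ".", gg$angle)
      paste(c(paste0("undefined:", lab[is.na(r)]),
              lab[!is.na(r) & !r]), collapse = ";")
    }, character(1L))
    res <- data.frame(chain = ch, start_index = d$res_index[starts],
                      start_auth = d$auth_number[starts],
                      stringsAsFactors = FALSE)
    res <- cbind(res, as.data.frame(checks))
    res$pass <- pass
    res$reason <- reason
    out[[ch]] <- res
  }
  res <- if (length(out)) do.call(rbind, out) else {
    tmpl <- data.frame(chain = character(), start_index = integer(),
                       start_auth = integer(), stringsAsFactors = FALSE)
    for (j in seq_len(nrow(gg)))
      tmpl[[paste0("ok_", gg$position[j], "_", gg$angle[j])]] <- logical()
    tmpl$pass <- logical(); tmpl$reason <- character()
    tmpl
  }
  rownames(res) <- NULL
  class(res) <- c("candidate_sites", "data.frame")
  res
}

#' Merge passing windows into candidate regions
#'
#' Maximal contiguous spans of passing windows, per chain.  Because a
#' printed range like "residues 11-20" does not say whether it spans window
#' starts or every residue covered by a passing window, both readings are
#' available: `"window-starts"` spans the x1 indices only, while
#' `"covered-residues"` spans the union of all residues of passing windows
#' (each window covers start..start+5).
#'
#' @param sites a `candidate_sites` table from [gate_scan()].
#' @param mode `"window-starts"` or `"covered-residues"`.
#' @param index_map optional data frame with `chain`, `res_index`,
#'   `auth_number` (e.g. a `dihedral_table`) used to report source-file
#'   numbers for region bounds; without it auth numbers repeat the indices.
#' @return data frame of class `region_table`: `chain`, `mode`,
#'   `start_index`, `end_index`, `start_auth`, `end_auth`, `n_windows`.
#' @export
merge_regions <- function(sites, mode = c("window-starts", "covered-residues"),
                          index_map = NULL) {
  mode <- match.arg(mode)
  out <- list()
  for (ch in unique(sites$chain)) {
    s <- sites[sites$chain == ch & sites$pass, , drop = FALSE]
    if (!nrow(s)) next
    covered <- if (mode == "window-starts") sort(unique(s$start_index))
               else sort(unique(unlist(lapply(s$start_index, function(x) x:(x + 5L)))))
    brk <- c(0L, which(diff(covered) > 1L), length(covered))
    for (b in seq_len(length(brk) - 1L)) {
      span <- covered[(brk[b] + 1L):brk[b + 1L]]
      lo <- span[1L]; hi <- span[length(span)]
      amap <- function(i) {
        if (is.null(index_map)) return(i)
        hit <- which(index_map$chain == ch & index_map$res_index == i)
        if (length(hit)) index_map$auth_number[hit[1L]] else NA_integer_
      }
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, mode = mode, start_index = lo, end_index = hi,
        start_auth = amap(lo), end_auth = amap(hi),
        n_windows = sum(s$start_index >= lo & s$start_index <= hi),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chain = character(), mode = character(),
               start_index = integer(), end_index = integer(),
               start_auth = integer(), end_auth = integer(),
               n_windows = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("region_table", "data.frame")
  res
}

#' Plan the point mutations creating a CxxCH motif
#'
#' For the 6-residue window starting at `start` (the x1 position) of
#' `sequence`, lists the substitutions turning positions C1, C2 and H into
#' `C`, `C` and `H`.  The residues between the cysteines (x2, x3) and the
#' preceding residue x1 are never modified, so at most three substitutions
#' are ever proposed.
#'
#' @param sequence one-letter amino-acid string.
#' @param start window start (x1 position), 1-based; `start + 5` must be
#'   within the sequence.
#' @return object of class `mutation_plan`: list with `start`,
#'   `window_before`, `window_after`, `substitutions` (data frame `offset`,
#'   `position`, `from`, `to`), `n_substitutions`, and `mutated_sequence`.
#' @export
plan_mutations <- function(sequence, start) {
  n <- nchar(sequence)
  if (start < 1L || start + 5L > n)
    stop("window [", start, ", ", start + 5L, "] out of sequence bounds (1..", n, ")")
  win <- strsplit(substr(sequence, start, start + 5L), "")[[1L]]
  target <- c(NA, "C", NA, NA, "C", "H")  # x1 C1 x2 x3 C2 H
  subs <- list()
  for (k in seq_along(target)) {
    if (!is.na(target[k]) && win[k] != target[k]) {
      subs[[length(subs) + 1L]] <- data.frame(
        offset = k, position = MOTIF_POSITIONS[k],
        from = win[k], to = target[k], stringsAsFactors = FALSE)
      win[k] <- target[k]
    }
  }
  subs <- if (length(subs)) do.call(rbind, subs) else
    data.frame(offset = integer(), position = character(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  mutated <- paste0(substr(sequence, 1L, start - 1L), paste(win, collapse = ""),
                    substr(sequence, start + 6L, n))
  structure(list(start = start,
                 window_before = substr(sequence, start, start + 5L),
                 window_after = paste(win, collapse = ""),
                 substitutions = subs,
                 n_substitutions = nrow(subs),
                 mutated_sequence = mutated),
            class = "mutation_plan")
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf("Mutation plan at window %d: %s -> %s (%d substitution%s)\n",
              x$start, x$window_before, x$window_after, x$n_substitutions,
              if (x$n_substitutions == 1L) "" else "s"))
  if (x$n_substitutions)
    print(x$substitutions, row.names = FALSE)
  invisible(x)
}

#' Plan a loop insertion carrying the heme-binding motif
#'
#' Inserts a 6-mer of layout `x1 C x x C H` after position `anchor` of the
#' sequence, the strategy used when no backbone window of the target gates
#' cleanly (e.g. a surface loop).  Removing the inserted span restores the
#' original sequence exactly.
#'
#' @param sequence one-letter amino-acid string.
#' @param anchor position after which to insert (0 inserts at the
#'   N-terminus; must lie in a loop of the target, which the caller
#'   designates).
#' @param motif the 6-mer to insert; must contain `CxxCH`.
#' @return object of class `insertion_plan`: list with `anchor`, `motif`,
#'   `sequence` (edited full-length sequence) and `motif_start` (x1 index in
#'   the edited sequence).
#' @export
plan_insertion <- function(sequence, anchor, motif = "ACAACH") {
  n <- nchar(sequence)
  if (anchor < 0L || anchor > n)
    stop("anchor ", anchor, " outside sequence (0..", n, ")")
  if (nchar(motif) != 6L)
    stop("insertion must be a 6-mer, got ", nchar(motif), " residues")
  if (!grepl("C[A-Z]{2}CH", motif))
    stop("inserted 6-mer '", motif, "' does not contain a CxxCH motif")
  edited <- paste0(substr(sequence, 1L, anchor), motif,
                   substr(sequence, anchor + 1L, n))
  structure(list(anchor = anchor, motif = motif, sequence = edited,
                 motif_start = anchor + 1L),
            class = "insertion_plan")
}

#' @export
print.insertion_plan <- function(x, ...) {
  cat(sprintf("Insertion plan: 6-mer %s after position %d (edited length %d)\n",
              x$motif, x$anchor, nchar(x$sequence)))
  invisible(x)
}
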