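# ICD-10 hierarchical grouping: code parsing, broad/narrow membership,
# the N >= 125 retention rule, comorbidity accounting and the unique case
# list used for multiclass classification.

#' Parse an ICD-10 code string
#'
#' Accepts second-level codes with an optional decimal subcode, e.g.
#' `"F32"` or `"G35.0"`.  Decimal subcodes roll up to their 2-digit parent
#' for all membership logic.
#'
#' @param code character scalar.
#' @return list with `letter`, `number` (integer), `sub` (subcode string or
#'   `NA`).
#' @export
icd10_parse <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([0-9]{2})(?:\\.([0-9A-Za-z]+))?$", code))[[1]]
  if (length(m) == 0)
    abort_format("unparseable ICD-10 code: '%s'", code)
  list(letter = m[2], number = as.integer(m[3]),
       sub = if (nzchar(m[4])) m[4] else NA_character_)
}

# Range labels are either a single code ("F32") or "F30-F39"; en dashes are
# tolerated. Ordering is lexicographic on (letter, number).
parse_range <- function(label) {
  parts <- strsplit(gsub("–", "-", label), "-", fixed = TRUE)[[1]]
  lo <- icd10_parse(parts[1])
  hi <- if (length(parts) > 1) icd10_parse(parts[2]) else lo
  list(lo = lo, hi = hi)
}

#' Test whether a code falls inside a range label
#' @param code ICD-10 code string (subcodes roll up).
#' @param range range label such as `"G35-G37"` or a single code.
#' @return logical scalar.
#' @export
icd10_in_range <- function(code, range) {
  c0 <- icd10_parse(code)
  r <- parse_range(range)
  c0$letter == r$lo$letter && c0$letter == r$hi$letter &&
    c0$number >= r$lo$number && c0$number <= r$hi$number
}

#' Default ICD-10 chapter V / VI hierarchy
#'
#' The first-level blocks of Chapter V (mental and behavioural disorders,
#' F00-F99) and Chapter VI (diseases of the nervous system, G00-G99), each
#' with every second-level code in the block as a narrow group.  A
#' convenience default, not a reconstruction of any particular cohort's
#' retained groups.
#'
#' @return list of `list(range =, narrow =)` entries.
#' @export
default_hierarchy <- function() {
  blocks <- c("F00-F09", "F10-F19", "F20-F29", "F30-F39", "F40-F48",
              "F50-F59", "F60-F69", "F70-F79", "F80-F89", "F90-F98",
              "F99-F99",
              "G00-G09", "G10-G14", "G20-G26", "G30-G32", "G35-G37",
              "G40-G47", "G50-G59", "G60-G64", "G70-G73", "G80-G83",
              "G90-G99")
  lapply(blocks, function(b) {
    r <- parse_range(b)
    list(range = b,
         narrow = sprintf("%s%02d", r$lo$letter, r$lo$number:r$hi$number))
  })
}

#' Assign participants to broad and narrow diagnostic groups
#'
#' A participant belongs to a narrow group iff any of their codes rolls up
#' to that second-level code, and to a broad group iff any code falls in
#' the block range.
#'
#' @param participants participant tibble with `id` and `icd10` list-column.
#' @param hierarchy list of `list(range =, narrow =)` entries (see
#'   [default_hierarchy()]); ranges must not overlap.
#' @return an `icd10_membership` object: lists `broad` and `narrow` mapping
#'   labels to case-id character vectors (possibly empty), plus
#'   `narrow_parent` mapping each narrow label to its broad range.
#' @export
assign_members <- function(participants, hierarchy = default_hierarchy()) {
  # flatten to (id, code) pairs and parse each distinct code once
  flat_id <- rep(participants$id, lengths(participants$icd10))
  flat_code <- unlist(participants$icd10) %||% character(0)
  ucodes <- unique(flat_code)
  m <- regmatches(ucodes, regexec("^([A-Z])([0-9]{2})(?:\\.([0-9A-Za-z]+))?$",
                                  ucodes))
  bad <- lengths(m) == 0
  if (any(bad))
    abort_format("participant %s: unparseable ICD-10 code '%s'",
                 flat_id[match(ucodes[bad][1], flat_code)], ucodes[bad][1])
  letter <- vapply(m, `[`, "", 2)
  number <- as.integer(vapply(m, `[`, "", 3))
  rolled_u <- sprintf("%s%02d", letter, number)
  rolled <- rolled_u[match(flat_code, ucodes)]

  by_narrow <- lapply(split(flat_id, rolled), unique)
  broad <- list(); narrow <- list(); narrow_parent <- character(0)
  for (entry in hierarchy) {
    r <- parse_range(entry$range)
    block_codes <- rolled_u[letter == r$lo$letter &
                              number >= r$lo$number & number <= r$hi$number]
    in_block <- rolled %in% block_codes
    broad[[entry$range]] <-
      participants$id[participants$id %in% unique(flat_id[in_block])]
    for (ncode in entry$narrow) {
      narrow[[ncode]] <- by_narrow[[ncode]] %||% character(0)
      narrow_parent[[ncode]] <- entry$range
    }
  }
  structure(list(broad = broad, narrow = narrow, narrow_parent = narrow_parent),
            class = "icd10_membership")
}

#' Retain diagnostic groups by the hierarchical minimum-size rule
#'
#' Narrow groups with at least `min_n` cases are retained.  For a broad
#' range in which no narrow group qualifies but the broad group itself has
#' at least `min_n` cases, the broad group is retained.  Ranges below the
#' threshold at both levels are dropped.  When a narrow group qualifies,
#' its sub-threshold siblings are dropped entirely, not merged.
#'
#' @param membership an `icd10_membership` from [assign_members()].
#' @param min_n retention threshold (default 125 cases).
#' @return list of `diagnostic_group` objects (`label`, `level`,
#'   `case_ids`), ordered by label.
#' @export
retain_groups <- function(membership, min_n = 125) {
  stopifnot(inherits(membership, "icd10_membership"))
  out <- list()
  for (range in names(membership$broad)) {
    kids <- names(membership$narrow_parent)[membership$narrow_parent == range]
    qualifying <- kids[vapply(kids, function(k)
      length(membership$narrow[[k]]) >= min_n, TRUE)]
    if (length(qualifying) > 0) {
      for (k in sort(qualifying))
        out[[k]] <- structure(list(label = k, level = "narrow",
                                   case_ids = membership$narrow[[k]]),
                              class = "diagnostic_group")
    } else if (length(membership$broad[[range]]) >= min_n) {
      out[[range]] <- structure(list(label = range, level = "broad",
                                     case_ids = membership$broad[[range]]),
                                class = "diagnostic_group")
    }
  }
  out[order(names(out))]
}

#' Comorbidity rate and pairwise overlap of retained groups
#'
#' @param groups list of `diagnostic_group` objects.
#' @return list with `overall_rate` (proportion of diagnosed individuals
#'   belonging to more than one group) and `pairwise_overlap` (matrix with
#'   `[a, b] = P(member of b | member of a)`; diagonal 1).
#' @export
comorbidity_stats <- function(groups) {
  if (length(groups) == 0) abort_config("need at least one retained group")
  labels <- vapply(groups, function(g) g$label, "")
  ids <- lapply(groups, function(g) g$case_ids)
  all_ids <- unique(unlist(ids))
  n_memberships <- rowSums(vapply(ids, function(s) all_ids %in% s,
                                  logical(length(all_ids))))
  overall <- if (length(all_ids) == 0) 0 else mean(n_memberships > 1)
  k <- length(groups)
  overlap <- matrix(0, k, k, dimnames = list(labels, labels))
  for (a in seq_len(k)) for (b in seq_len(k))
    overlap[a, b] <- length(intersect(ids[[a]], ids[[b]])) / length(ids[[a]])
  list(overall_rate = overall, pairwise_overlap = overlap)
}

#' Unique case list: drop every multi-group individual
#'
#' Restricts each retained group to the individuals who belong to exactly
#' one of the retained groups, yielding pairwise disjoint case sets (as
#' required for the multiclass formulation).
#'
#' @param groups list of `diagnostic_group` objects.
#' @return named list label -> case-id vector; sets are pairwise disjoint.
#' @export
unique_case_list <- function(groups) {
  ids <- lapply(groups, function(g) g$case_ids)
  counts <- table(unlist(ids))
  singles <- names(counts)[counts == 1]
  out <- lapply(ids, function(s) s[s %in% singles])
  names(out) <- vapply(groups, function(g) g$label, "")
  out
}
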