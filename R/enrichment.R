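#' Read a gene-set collection from a GMT file
#'
#' One term per tab-separated line: term id, description, then member gene
#' ids. Members are whitespace-trimmed and uppercased; terms left with no
#' members are dropped with a warning; duplicate term ids and lines with
#' fewer than three fields are errors naming the line number.
#'
#' @param path Path to a GMT file.
#' @return A gene-set tibble: `term_id`, `term_name`, `members`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields", i))
    }
    members <- toupper(trimws(f[-(1:2)]))
    members <- unique(members[nzchar(members)])
    tibble(term_id = f[1], term_name = f[2], members = list(sort(members)))
  })
  out <- bind_rows(parsed)
  if (anyDuplicated(out$term_id)) {
    abort(sprintf("duplicate term id in GMT: %s",
                  out$term_id[duplicated(out$term_id)][1]))
  }
  empty <- lengths(out$members) == 0
  if (any(empty)) {
    warn(sprintf("dropped %d GMT term(s) with no members", sum(empty)))
    out <- out[!empty, ]
  }
  out
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Gene-set tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  assert_columns(sets, c("term_id", "term_name", "members"), "gene-set collection")
  lines <- purrr::pmap_chr(sets, function(term_id, term_name, members, ...) {
    paste(c(term_id, term_name, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene list
#'
#' For every term, the upper-tail hypergeometric probability of observing
#' at least the seen overlap when drawing `|query|` genes from the
#' background with the term's in-background members marked as successes.
#' P-values are BH-adjusted across all tested terms; reported terms have
#' adjusted p strictly below `p_max` and non-zero overlap, sorted by
#' ascending p.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param sets Gene-set tibble as returned by [read_gmt()].
#' @param p_max Adjusted-p threshold (strict), default 0.05.
#' @return Tibble `term_id`, `term_name`, `overlap`, `term_size`,
#'   `query_size`, `background_size`, `p`, `p_adj`.
#' @export
enrich <- function(query, background, sets, p_max = 0.05) {
  assert_columns(sets, c("term_id", "term_name", "members"), "gene-set collection")
  query <- unique(query)
  background <- unique(background)
  if (length(setdiff(query, background)) > 0) {
    abort("query genes must all be in the background universe")
  }
  empty <- tibble(term_id = character(0), term_name = character(0),
                  overlap = integer(0), term_size = integer(0),
                  query_size = integer(0), background_size = integer(0),
                  p = double(0), p_adj = double(0))
  if (length(query) == 0) {
    warn("empty query: no enrichment computed")
    return(empty)
  }
  if (nrow(sets) == 0) return(empty)
  n_bg <- length(background)
  n_q <- length(query)
  res <- sets |>
    mutate(term_size = purrr::map_int(.data$members,
                                      ~ length(intersect(.x, background))),
           overlap = purrr::map_int(.data$members,
                                    ~ length(intersect(.x, query))),
           query_size = n_q, background_size = n_bg,
           p = phyper(.data$overlap - 1, .data$term_size,
                      n_bg - .data$term_size, n_q, lower.tail = FALSE)) |>
    mutate(p_adj = bh_adjust(.data$p))
  res |>
    filter(.data$p_adj < p_max, .data$overlap > 0) |>
    select("term_id", "term_name", "overlap", "term_size", "query_size",
           "background_size", "p", "p_adj") |>
    arrange(.data$p, .data$term_id)
}
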