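#' Write a rule base to YAML
#'
#' Serializes partitions (universe bounds, units, named sets with their
#' `a,b,c,d` breakpoints) and the rule list.  Numeric values are written at
#' full double precision so that a read/write round trip is loss-free.
#'
#' @param rb a [rule_base()].
#' @param path file path to write (conventionally `rules.yaml`).
#' @return `path`, invisibly.
#' @export
write_rule_base <- function(rb, path) {
  stopifnot(inherits(rb, "rule_base"))
  part_to_list <- function(p) {
    list(universe = list(lo = p$universe[1], hi = p$universe[2],
                         units = p$units),
         sets = lapply(unname(p$sets), function(s)
           list(name = s$name, a = s$a, b = s$b, c = s$c, d = s$d)))
  }
  doc <- list(
    temperature = part_to_list(rb$temp_partition),
    r0 = part_to_list(rb$r0_partition),
    rules = lapply(rb$rules, function(r)
      list(antecedent = r$antecedent, consequent = r$consequent)))
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Read a rule base from YAML
#'
#' @param path file written by [write_rule_base()] (or hand-authored with
#'   the same layout).
#' @return a [rule_base()].
#' @export
read_rule_base <- function(path) {
  if (!file.exists(path)) stop(sprintf("rule-base file not found: %s", path))
  doc <- yaml::read_yaml(path)
  for (k in c("temperature", "r0", "rules"))
    if (is.null(doc[[k]])) stop(sprintf("rule-base YAML is missing '%s'", k))
  list_to_part <- function(l) {
    sets <- lapply(l$sets, function(s)
      trapezoid_mf(s$name, s$a, s$b, s$c, s$d))
    fuzzy_partition(c(l$universe$lo, l$universe$hi), sets,
                    units = l$universe$units %||% "")
  }
  rules <- lapply(doc$rules, function(r) fuzzy_rule(r$antecedent, r$consequent))
  rule_base(list_to_part(doc$temperature), list_to_part(doc$r0), rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
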