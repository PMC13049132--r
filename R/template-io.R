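#' Read an objective/constraint template from YAML
#'
#' Templates list dose objectives (structure, function id, weight, dose
#' parameters in total Gy(RBE)) and per-structure box dose constraints. When
#' `structures` is given, rows referring to structures that are absent or
#' empty in the phantom are dropped, so one clinical template serves phantoms
#' with different optional organs at risk.
#'
#' @param path YAML file.
#' @param structures optional [structure_set()] used to filter rows.
#' @return List with `objectives` (list of [objective_spec()]) and
#'   `constraints` (list of [constraint_spec()]).
#' @export
read_plan_template <- function(path, structures = NULL) {
  tpl <- yaml::read_yaml(path)
  obj <- lapply(tpl$objectives, function(row) {
    pars <- row[setdiff(names(row), c("structure", "function", "weight"))]
    do.call(objective_spec,
            c(list(structure = row$structure, function_id = row$`function`,
                   weight = row$weight), pars))
  })
  con <- lapply(tpl$constraints, function(row)
    constraint_spec(row$structure, row$lower %||% 0, row$upper %||% Inf))
  if (!is.null(structures)) {
    have <- names(Filter(any, structures$masks))
    obj <- Filter(function(o) o$function_id %in% polo_ids ||
                    o$structure %in% have, obj)
    con <- Filter(function(cs) cs$structure %in% have, con)
  }
  list(objectives = obj, constraints = con)
}

#' @rdname read_plan_template
#' @param template list as returned by [read_plan_template()].
#' @export
write_plan_template <- function(template, path) {
  rows_o <- lapply(template$objectives, function(o)
    c(list(structure = o$structure, `function` = o$function_id,
           weight = o$weight), o$parameters))
  rows_c <- lapply(template$constraints, function(cs)
    list(structure = cs$structure, lower = cs$lower, upper = cs$upper))
  yaml::write_yaml(list(objectives = rows_o, constraints = rows_c), path)
  invisible(path)
}
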