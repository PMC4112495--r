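rules_cache <- new.env(parent = emptyenv())

#' The diagnostic rule table
#'
#' Loads the versioned declarative rule table shipped with the package
#' (`inst/extdata/armstrong_rules.yaml`): the onset/duration gates, the
#' probable-CBD demographic and genetic requirements, the phenotype routes
#' for probable and possible CBD, the eight exclusion criteria, and the
#' precedence order used to assign a single primary label.
#'
#' @param path Optional path to an alternative YAML rule table.
#' @return A named list mirroring the YAML document.
#' @export
cbd_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(rules_cache$default)) {
      default_path <- system.file("extdata", "armstrong_rules.yaml",
                                  package = "cbdcriteria", mustWork = TRUE)
      rules_cache$default <- yaml::read_yaml(default_path)
    }
    return(rules_cache$default)
  }
  yaml::read_yaml(path)
}
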