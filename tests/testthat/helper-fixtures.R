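# Shared fixtures, built once per test run (everything is generated in
# code; nothing is read from disk).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

thorax_template <- function() {
  fixture("thorax_template", function() build_template("thorax-like", c(64, 64), seed = 1))
}

thorax_basis <- function() {
  fixture("thorax_basis", function() build_deformation_basis(thorax_template(), k = 3, seed = 2))
}

# small labelled population with rasterized labels (n = 20)
thorax_population <- function() {
  fixture("thorax_population", function() {
    sample_population(thorax_template(), thorax_basis(), n = 20, seed = 3,
                      representations = c("landmarks", "label"))
  })
}

# larger landmarks-only population for PCA work (n = 80)
landmark_population <- function() {
  fixture("landmark_population", function() {
    sample_population(thorax_template(), thorax_basis(), n = 80, seed = 4,
                      representations = "landmarks")
  })
}

# register an S3 method for a throwaway stub class, cleaned up after the test
stub_method <- function(generic, class, fn, env = parent.frame()) {
  name <- paste0(generic, ".", class)
  assign(name, fn, envir = globalenv())
  withr::defer(rm(list = name, envir = globalenv()), envir = env)
}
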