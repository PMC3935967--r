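# Shared small fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

tiny_native <- function() cached("tiny_native", function()
  build_native(c("H12", "E8", "E8", "H8"), seed = 7, model_id = "tiny"))

tiny_profile <- function() cached("tiny_profile", function()
  profile_from_structure(tiny_native(), seed = 3))

helix_native <- function() cached("helix_native", function()
  build_native(c("H10", "H8", "H9"), seed = 5, model_id = "helices"))
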