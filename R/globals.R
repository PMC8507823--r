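# data.table non-standard-evaluation columns
utils::globalVariables(c(
  ".", "..author", "anger", "author", "community", "compound", "cohort",
  "created_utc", "empty_text", "fear", "g", "group", "happiness", "key",
  "kind", "lag", "mean_compound", "mix_key", "n_items", "n_participants",
  "n_tokens", "posts_per_participant", "sadness", "significant", "stream",
  "surprise", "term", "title", "week"))
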