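{
  "dataset": "ancientsinglegenome-hostassociated",
  "table_type": "samples",
  "key_columns": ["project_name", "sample_name"],
  "columns": [
    {"name": "project_name", "value_kind": "free_text"},
    {"name": "publication_year", "value_kind": "integer"},
    {"name": "publication_doi", "value_kind": "doi"},
    {"name": "site_name", "value_kind": "free_text"},
    {"name": "latitude", "value_kind": "number", "missing_token_allowed": true},
    {"name": "longitude", "value_kind": "number", "missing_token_allowed": true},
    {"name": "geo_loc_name", "value_kind": "free_text"},
    {"name": "sample_name", "value_kind": "free_text"},
    {"name": "sample_host", "value_kind": "free_text"},
    {"name": "sample_age", "value_kind": "integer", "missing_token_allowed": true},
    {"name": "material", "value_kind": "free_text"},
    {"name": "archive", "value_kind": "enum", "enum": "archive"},
    {"name": "archive_project", "value_kind": "accession_list"},
    {"name": "archive_accession", "value_kind": "accession_list"}
  ]
}
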