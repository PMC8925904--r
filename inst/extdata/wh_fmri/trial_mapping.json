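{
  "comment": "By-trial to by-event mapping for the face-perception fMRI tables. The anchor is the face presentation onset (the row onset). The reference point of each stored delay must be stated explicitly; here cross_duration is the time the cross was shown BEFORE the anchor, duration is the face display length, and response_time is measured from the anchor (face onset) -- a documented assumption, since the original distribution does not state the reference.",
  "anchor_column": "onset",
  "anchor_event": "show_face",
  "derived_events": [
    {"event_name": "show_cross", "source_column": "cross_duration", "sign": "before", "role": "onset-delta"},
    {"event_name": "show_face", "source_column": null, "sign": "after", "role": "anchor"},
    {"event_name": "show_circle", "source_column": "duration", "sign": "after", "role": "duration-from-anchor"},
    {"event_name": "key_press", "source_column": "response_time", "sign": "after", "role": "onset-delta"}
  ],
  "pass_through": ["stim_type", "trigger", "button_pushed", "stim_file"]
}
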