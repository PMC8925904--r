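{
  "onset": {
    "Description": "Time of the event marker in seconds relative to the start of the recording."
  },
  "duration": {
    "Description": "Duration of the event in seconds; n/a when the extent is conveyed by Onset/Offset annotation."
  },
  "sample": {
    "Description": "Data sample index corresponding to the event marker."
  },
  "event_type": {
    "Description": "Type of event marker.",
    "Levels": {
      "setup_left_sym": "Recording setup meta-event: left index finger means more symmetric.",
      "setup_right_sym": "Recording setup meta-event: right index finger means more symmetric.",
      "show_face_initial": "First face display of the run; no preceding cross marker was recorded.",
      "show_face": "Display of a face image, ending the cross-only display.",
      "show_cross": "Display of the white fixation cross, ending the circle-only display.",
      "show_circle": "Display of the white circle, ending the face display.",
      "left_press": "Participant key press with the left index finger.",
      "right_press": "Participant key press with the right index finger."
    },
    "HED": {
      "setup_left_sym": "Experiment-control, (Def/Left-sym-cond, Onset)",
      "setup_right_sym": "Experiment-control, (Def/Right-sym-cond, Onset)",
      "show_face_initial": "Sensory-event, Experimental-stimulus, (Def/Face-image, Onset), (Def/Blink-inhibition, Onset), (Def/Fixation-task, Onset)",
      "show_face": "Sensory-event, Experimental-stimulus, (Def/Face-image, Onset), (Def/Blink-inhibition, Onset), (Def/Cross-only, Offset)",
      "show_cross": "Sensory-event, Cue, (Def/Cross-only, Onset), (Def/Fixation-task, Onset), (Def/Circle-only, Offset)",
      "show_circle": "Sensory-event, Cue, (Def/Circle-only, Onset), (Def/Face-image, Offset), (Def/Blink-inhibition, Offset), (Def/Fixation-task, Offset)",
      "left_press": "Agent-action, Participant-response, Def/Press-left-finger",
      "right_press": "Agent-action, Participant-response, Def/Press-right-finger"
    }
  },
  "face_type": {
    "Description": "Level of the face type factor for face presentation events.",
    "Levels": {
      "famous_face": "A face that should be recognized by the participants.",
      "unfamiliar_face": "A face that should not be recognized by the participants.",
      "scrambled_face": "A scrambled face image generated by the face 2D FFT."
    },
    "HED": {
      "famous_face": "Def/Famous-face-cond",
      "unfamiliar_face": "Def/Unfamiliar-face-cond",
      "scrambled_face": "Def/Scrambled-face-cond"
    }
  },
  "rep_status": {
    "Description": "Level of the repetition status factor for face presentation events.",
    "Levels": {
      "first_show": "Factor level indicating the first display of this face.",
      "immediate_repeat": "Factor level indicating this face was the same as the previous one.",
      "delayed_repeat": "Factor level indicating this face was seen 5 to 15 trials ago."
    },
    "HED": {
      "first_show": "Def/First-show-cond",
      "immediate_repeat": "Def/Immediate-repeat-cond",
      "delayed_repeat": "Def/Delayed-repeat-cond"
    }
  },
  "rep_lag": {
    "Description": "Number of face presentations since this face was first shown; n/a on first showings.",
    "HED": "(Face, Item-interval/#)"
  },
  "value": {
    "Description": "Trigger code emitted by the experiment control software; retained for provenance, not annotated."
  },
  "stim_file": {
    "Description": "File name of the presented stimulus image.",
    "HED": "(Image, Pathname/#)"
  },
  "hed_def_sensory": {
    "Description": "Definitions of the sensory presentation concepts.",
    "HED": {
      "face_image_def": "(Definition/Face-image, (Visual-presentation, (Image, Face), (White, Cross)))",
      "cross_only_def": "(Definition/Cross-only, (Visual-presentation, (White, Cross)))",
      "circle_only_def": "(Definition/Circle-only, (Visual-presentation, (White, Circle)))"
    }
  },
  "hed_def_actions": {
    "Description": "Definitions of the participant action concepts.",
    "HED": {
      "press_left_def": "(Definition/Press-left-finger, ((Index-finger, Left-side-of), (Press, Keyboard-key)))",
      "press_right_def": "(Definition/Press-right-finger, ((Index-finger, Right-side-of), (Press, Keyboard-key)))"
    }
  },
  "hed_def_tasks": {
    "Description": "Definitions of the instructed eye-control tasks.",
    "HED": {
      "fixation_task_def": "(Definition/Fixation-task, (Experiment-participant, (Fixate, Cross)))",
      "blink_inhibition_def": "(Definition/Blink-inhibition, (Experiment-participant, Inhibit-blinks))"
    }
  },
  "hed_def_conds": {
    "Description": "Definitions encoding the experimental design factors and levels.",
    "HED": {
      "famous_cond_def": "(Definition/Famous-face-cond, (Condition-variable/Face-type, (Image, (Face, Famous))))",
      "unfamiliar_cond_def": "(Definition/Unfamiliar-face-cond, (Condition-variable/Face-type, (Image, (Face, Unfamiliar))))",
      "scrambled_cond_def": "(Definition/Scrambled-face-cond, (Condition-variable/Face-type, (Image, (Face, Disordered))))",
      "first_show_cond_def": "(Definition/First-show-cond, (Condition-variable/Repetition-status, Item-count/1))",
      "immediate_repeat_cond_def": "(Definition/Immediate-repeat-cond, (Condition-variable/Repetition-status, Item-count/2, Item-interval/1))",
      "delayed_repeat_cond_def": "(Definition/Delayed-repeat-cond, (Condition-variable/Repetition-status, Item-count/2))",
      "left_sym_cond_def": "(Definition/Left-sym-cond, (Condition-variable/Key-assignment, ((Index-finger, Left-side-of), Symmetrical)))",
      "right_sym_cond_def": "(Definition/Right-sym-cond, (Condition-variable/Key-assignment, ((Index-finger, Right-side-of), Symmetrical)))"
    }
  }
}
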