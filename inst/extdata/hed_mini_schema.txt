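# hedlite mini vocabulary, version 1.0
# One node per line; nesting by two-space indentation; a lone "#" child marks
# a node that takes a /value suffix; text after " ; " is a description.
Event ; Something that happens at a point or during a span of time in the recording.
  Sensory-event ; A sensory presentation reaching the participant.
  Agent-action ; An action performed by an agent, typically the participant.
  Data-feature ; A computed or observed feature of the recorded data.
  Experiment-control ; An action of the experiment control software or experimenter.
  Experiment-procedure ; A procedural step of the experiment.
  Experiment-structure ; A marker of the structural organization of the recording.
  Measurement-event ; A measurement acquisition marker.
Agent ; An entity that can act.
  Human-agent ; A human.
    Experiment-participant ; The person whose data are being recorded.
    Experimenter ; The person running the experiment.
  Software-agent ; A software system acting autonomously.
Action ; Something an agent does.
  Press ; Push against something, as a key or button.
  Release ; Let go of something being pressed or held.
  Fixate ; Hold the eye gaze on a target.
  Inhibit-blinks ; Deliberately refrain from blinking.
  Perform ; Carry out an activity.
Item ; A thing with physical or virtual extent.
  Object ; A tangible or depicted thing.
    Geometric-object ; An abstract geometric form.
      2D-shape ; A two-dimensional shape.
        Ellipse ; A closed conic curve.
          Circle ; An ellipse with equal axes.
        Cross ; Two intersecting strokes.
        Rectangle ; A four-sided right-angled shape.
          Square ; A rectangle with equal sides.
        Triangle ; A three-sided shape.
      3D-shape ; A three-dimensional shape.
    Man-made-object ; A manufactured thing.
      Media ; A presentation medium.
        Image ; A two-dimensional picture.
        Media-clip ; A playable audio or video segment.
      Device ; A piece of equipment.
        IO-device ; A device for input or output.
          Input-device ; A device for user input.
            Keyboard ; A bank of keys.
              Keyboard-key ; A single key of a keyboard.
        Computer-screen ; A visual display device.
  Biological-item ; A thing from a living organism.
    Anatomical-item ; A body structure.
      Body-part ; A part of the body.
        Head ; The head.
          Face ; The face.
        Upper-extremity ; Arm, wrist and hand.
          Hand ; The hand.
            Index-finger ; The finger next to the thumb.
            Thumb ; The thumb.
  Language-item ; A linguistic unit.
    Word ; A single word.
Property ; An attribute, quality or role of something.
  Informational-property ; Identifying or descriptive metadata.
    Label ; A short identifying text.
      #
    Description ; A free-text description.
      #
    Pathname ; A file path or file name.
      #
    ID ; An identifier code.
      #
  Sensory-property ; A property of sensory presentation.
    Sensory-presentation ; The modality through which something is presented.
      Visual-presentation ; Presented through the visual modality.
      Auditory-presentation ; Presented through the auditory modality.
      Tactile-presentation ; Presented through touch.
    Sensory-attribute ; A perceptual attribute of a presentation.
      Visual-attribute ; A visually perceived attribute.
        Color ; A perceived color.
          White ; White.
          Black ; Black.
          Gray ; Gray.
          Red ; Red.
          Green ; Green.
          Blue ; Blue.
      Symmetrical ; Having mirror symmetry.
      Asymmetrical ; Lacking mirror symmetry.
  Cognitive-property ; A cognitive status of an item for the participant.
    Famous ; Widely recognizable.
    Unfamiliar ; Not previously known to the participant.
    Disordered ; Scrambled or structurally randomized.
    Novel ; Not encountered before in the session.
  Organizational-property ; A property organizing events and annotations.
    Condition-variable ; An experimental design factor; the value names the factor.
      #
    Definition ; Declares a named annotation concept; the value is the name.
      #
    Def ; A reference to a defined concept; the value is the name.
      #
    Def-expand ; An expanded reference to a defined concept.
      #
    Event-context ; Grouping of the event processes ongoing at an event.
    Experimental-trial ; A trial of the experiment; the value is the trial index.
      #
    Time-block ; A named span of the recording.
      #
  Data-property ; A property of the recorded data values.
    Quantitative-value ; A numeric quantity.
      Item-count ; Number of occurrences of an item; the value is the count.
        #
      Item-interval ; Position within a sequence of item occurrences.
        #
    Data-marker ; A marker within the data stream.
      Temporal-marker ; A marker of a point in event time.
        Onset ; Marks the start of an event process.
        Offset ; Marks the end of an event process.
        Inset ; Marks an intermediate point of an event process.
Task ; The role something plays in the experimental task.
  Task-event-role ; The task role of an event.
    Experimental-stimulus ; Part of the planned stimulus presentation.
    Participant-response ; An instructed participant response.
    Cue ; A signal guiding participant behavior.
    Feedback ; Information returned about performance.
  Task-action-type ; How an action relates to the task.
    Appropriate-action ; An action conforming to the instructions.
    Incorrect-action ; An action violating the instructions.
Relation ; A relation holding between items.
  Spatial-relation ; A relation in space.
    Left-side-of ; To the left of a reference.
    Right-side-of ; To the right of a reference.
    Center-of ; At the center of a reference.
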