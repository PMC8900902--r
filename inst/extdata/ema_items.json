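{
  "version": "1.0",
  "scales": {
    "ordinal4": {"type": "integer", "min": 1, "max": 4},
    "slider": {"type": "integer", "min": 0, "max": 100}
  },
  "affect_items": ["upset", "nervous", "stressed", "could_not_cope",
                   "happy", "great", "cheerful", "joyful"],
  "time_triggered": [
    {"id": "affect", "scale": "ordinal4", "multi_item": true}
  ],
  "event_triggered": {
    "first_question": {
      "id": "eating_confirmation",
      "options": ["yes", "no"]
    },
    "yes": [
      {"id": "eating_type", "options": ["meal", "snack", "drink_only"]},
      {"id": "social_context",
       "options": ["nobody", "spouse_partner", "children", "mother", "father",
                   "sisters", "brothers", "grandparent", "other_family",
                   "friends", "other_people"],
       "multi_select": true},
      {"id": "started_eating", "scale": "ordinal4", "multi_item": true,
       "items": ["food_appeal", "others_eating", "sad", "bored", "angry",
                 "tired", "anxious", "family_wanted"]},
      {"id": "kept_eating", "scale": "ordinal4", "multi_item": true,
       "items": ["food_appeal", "others_eating", "sad", "bored", "angry",
                 "tired", "anxious", "finish_plate"]},
      {"id": "hunger", "scale": "slider"},
      {"id": "satiety", "scale": "slider"},
      {"id": "mindful_eating", "scale": "ordinal4", "multi_item": true,
       "items": ["thoughts_wandering", "thinking_todo", "ate_quickly"]},
      {"id": "affect", "scale": "ordinal4", "multi_item": true}
    ],
    "no": [
      {"id": "activity", "free_text": true},
      {"id": "affect", "scale": "ordinal4", "multi_item": true}
    ]
  }
}
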