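{
  "cycle_id": "demo_cycle",
  "entries": {
    "1": {
      "breakfast": {
        "regular_1800": [
          {"item_id": "oatmeal", "servings": 1},
          {"item_id": "scrambled_egg", "servings": 1},
          {"item_id": "toast_wheat", "servings": 1},
          {"item_id": "orange_juice", "servings": 1},
          {"item_id": "coffee", "servings": 1}
        ],
        "full_liquid": [
          {"item_id": "cream_soup", "servings": 1},
          {"item_id": "orange_juice", "servings": 1},
          {"item_id": "milk_2pct", "servings": 1},
          {"item_id": "gelatin", "servings": 1}
        ]
      },
      "lunch": {
        "regular_1800": [
          {"item_id": "beef_stew", "servings": 1},
          {"item_id": "dinner_roll", "servings": 1},
          {"item_id": "fruit_cup", "servings": 1},
          {"item_id": "milk_2pct", "servings": 1}
        ],
        "full_liquid": [
          {"item_id": "cream_soup", "servings": 1},
          {"item_id": "apple_juice", "servings": 1},
          {"item_id": "vanilla_pudding", "servings": 1}
        ]
      },
      "dinner": {
        "regular_1800": [
          {"item_id": "chicken_breast", "servings": 1},
          {"item_id": "mashed_potato", "servings": 1},
          {"item_id": "green_beans", "servings": 2},
          {"item_id": "dinner_roll", "servings": 1},
          {"item_id": "milk_2pct", "servings": 1}
        ],
        "full_liquid": [
          {"item_id": "cream_soup", "servings": 1},
          {"item_id": "apple_juice", "servings": 1},
          {"item_id": "gelatin", "servings": 1},
          {"item_id": "vanilla_pudding", "servings": 1}
        ]
      }
    }
  }
}
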