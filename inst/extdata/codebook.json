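{
  "version": "1.0",
  "survey_groups": [
    {
      "id": "dark_green_leafy_veg",
      "label": "Dark green leafy vegetables",
      "mddw_group": "vit_a_dark_green_veg",
      "pdqs_group": "dark_green_leafy_veg",
      "pdqs_healthy": true
    },
    {
      "id": "other_vit_a_fruit_veg",
      "label": "Other vitamin A-rich fruits and vegetables (incl. red/orange produce)",
      "mddw_group": "other_vit_a_fruit_veg",
      "pdqs_group": "other_vit_a_fruit_veg",
      "pdqs_healthy": true
    },
    {
      "id": "cruciferous_veg",
      "label": "Cruciferous vegetables",
      "mddw_group": "other_veg",
      "pdqs_group": "cruciferous_veg",
      "pdqs_healthy": true
    },
    {
      "id": "other_veg",
      "label": "Other vegetables",
      "mddw_group": "other_veg",
      "pdqs_group": "other_veg",
      "pdqs_healthy": true
    },
    {
      "id": "citrus_fruits",
      "label": "Whole citrus fruits",
      "mddw_group": "other_fruits",
      "pdqs_group": "citrus_fruits",
      "pdqs_healthy": true
    },
    {
      "id": "other_fruits",
      "label": "Other fruits",
      "mddw_group": "other_fruits",
      "pdqs_group": "other_fruits",
      "pdqs_healthy": true
    },
    {
      "id": "fish",
      "label": "Fish",
      "mddw_group": "meat_poultry_fish",
      "pdqs_group": "fish",
      "pdqs_healthy": true
    },
    {
      "id": "eggs",
      "label": "Eggs",
      "mddw_group": "eggs",
      "pdqs_group": "eggs",
      "pdqs_healthy": true
    },
    {
      "id": "poultry",
      "label": "Poultry",
      "mddw_group": "meat_poultry_fish",
      "pdqs_group": "poultry",
      "pdqs_healthy": true
    },
    {
      "id": "legumes",
      "label": "Legumes (beans, peas, lentils)",
      "mddw_group": "legumes",
      "pdqs_group": "legumes",
      "pdqs_healthy": true
    },
    {
      "id": "nuts_seeds",
      "label": "Nuts and seeds",
      "mddw_group": "nuts_seeds",
      "pdqs_group": "nuts_seeds",
      "pdqs_healthy": true
    },
    {
      "id": "dairy",
      "label": "Dairy",
      "mddw_group": "dairy",
      "pdqs_group": "dairy",
      "pdqs_healthy": true
    },
    {
      "id": "whole_grains",
      "label": "Whole grains",
      "mddw_group": "grains_roots_tubers",
      "pdqs_group": "whole_grains",
      "pdqs_healthy": true
    },
    {
      "id": "liquid_veg_oils",
      "label": "Liquid vegetable oils",
      "mddw_group": "none",
      "pdqs_group": "liquid_veg_oils",
      "pdqs_healthy": true
    },
    {
      "id": "red_meat",
      "label": "Red meat",
      "mddw_group": "meat_poultry_fish",
      "pdqs_group": "red_meat",
      "pdqs_healthy": false
    },
    {
      "id": "processed_meat",
      "label": "Processed meats",
      "mddw_group": "meat_poultry_fish",
      "pdqs_group": "processed_meat",
      "pdqs_healthy": false
    },
    {
      "id": "refined_grains",
      "label": "Refined grains and baked goods (incl. maize-flour products)",
      "mddw_group": "grains_roots_tubers",
      "pdqs_group": "refined_grains",
      "pdqs_healthy": false
    },
    {
      "id": "ssb",
      "label": "Sugar-sweetened beverages",
      "mddw_group": "none",
      "pdqs_group": "ssb",
      "pdqs_healthy": false
    },
    {
      "id": "desserts_sweets",
      "label": "Desserts and sweets",
      "mddw_group": "none",
      "pdqs_group": "desserts_sweets",
      "pdqs_healthy": false
    },
    {
      "id": "roots_tubers",
      "label": "Roots and tubers",
      "mddw_group": "grains_roots_tubers",
      "pdqs_group": "roots_tubers",
      "pdqs_healthy": false
    }
  ],
  "mddw_groups": [
    {
      "id": "grains_roots_tubers",
      "label": "Grains, white roots and tubers, and plantains"
    },
    {
      "id": "legumes",
      "label": "Legumes (beans, peas and lentils)"
    },
    {
      "id": "nuts_seeds",
      "label": "Nuts and seeds"
    },
    {
      "id": "dairy",
      "label": "Dairy"
    },
    {
      "id": "meat_poultry_fish",
      "label": "Meats, poultry and fish"
    },
    {
      "id": "eggs",
      "label": "Eggs"
    },
    {
      "id": "vit_a_dark_green_veg",
      "label": "Vitamin A-rich dark green vegetables"
    },
    {
      "id": "other_vit_a_fruit_veg",
      "label": "Other vitamin A-rich fruits and vegetables"
    },
    {
      "id": "other_veg",
      "label": "Other vegetables"
    },
    {
      "id": "other_fruits",
      "label": "Other fruits"
    }
  ],
  "sites": [
    {
      "site": "nouna",
      "country": "burkina_faso",
      "locality": "rural"
    },
    {
      "site": "ouagadougou",
      "country": "burkina_faso",
      "locality": "urban"
    },
    {
      "site": "kersa",
      "country": "ethiopia",
      "locality": "rural"
    },
    {
      "site": "addis_ababa",
      "country": "ethiopia",
      "locality": "urban"
    },
    {
      "site": "ibadan",
      "country": "nigeria",
      "locality": "rural"
    },
    {
      "site": "lagos",
      "country": "nigeria",
      "locality": "urban"
    }
  ],
  "site_masks": {
    "kersa": "other_vit_a_fruit_veg",
    "addis_ababa": ["citrus_fruits", "other_fruits"]
  }
}
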