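entity_id,display_name,kind,category,access_home,access_preparer
/m/syn001,bread,food,bread_and_flatbread,,
/m/syn002,flatbread,food,bread_and_flatbread,,
/m/syn003,baguette,food,bread_and_flatbread,,
/m/syn004,croissant,food,pastry_and_bakery,,
/m/syn005,cake,food,pastry_and_bakery,,
/m/syn006,cookie,food,pastry_and_bakery,,
/m/syn007,carrot,food,vegetables,,
/m/syn008,spinach,food,vegetables,,
/m/syn009,tomato,food,vegetables,,
/m/syn010,ice cream,food,desserts,,
/m/syn011,pudding,food,desserts,,
/m/syn012,brownie,food,desserts,,
/m/syn101,recipe,access_mode,,home,household
/m/syn102,cooking,access_mode,,home,household
/m/syn103,baking,access_mode,,home,household
/m/syn104,grocery store,access_mode,,home,household
/m/syn105,supermarket,access_mode,,home,household
/m/syn106,food delivery,access_mode,,home,third_party
/m/syn107,take-out,access_mode,,home,third_party
/m/syn108,drive-in,access_mode,,home,third_party
/m/syn109,picnic,access_mode,,outside,household
/m/syn110,barbecue,access_mode,,outside,household
/m/syn111,lunchbox,access_mode,,outside,household
/m/syn112,restaurant,access_mode,,outside,third_party
/m/syn113,cafeteria,access_mode,,outside,third_party
/m/syn114,cafe,access_mode,,outside,third_party
/m/syn115,diner,access_mode,,outside,third_party
/m/syn116,food festival,access_mode,,outside,third_party
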