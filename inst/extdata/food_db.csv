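item_id,description,serving_label,serving_weight_g,energy_kcal,protein_g,fat_sat_g,fat_unsat_g,carb_g,sodium_mg,vitamin_c_mg
oatmeal,Oatmeal with margarine,1 cup,240,160,6,1,2.5,27,115,0
scrambled_egg,Scrambled egg,2 eggs,120,180,12,4,6,2,340,0
toast_wheat,Whole wheat toast,2 slices,60,140,6,0.5,1.5,24,260,0
orange_juice,Orange juice,120 mL,124,56,0.9,0,0,13,1,50
milk_2pct,2% milk,240 mL,244,122,8,3,1.8,12,115,0
coffee,Coffee with creamer,180 mL,185,30,0.5,1,0.5,3,15,0
chicken_breast,Baked chicken breast,1 breast,140,230,43,1.5,3.5,0,104,0
mashed_potato,Mashed potatoes with gravy,1 cup,210,214,4,2.5,4.5,35,620,20
green_beans,Seasoned green beans,0.5 cup,68,22,1.2,0,0.2,5,190,8
dinner_roll,Dinner roll with margarine,1 roll,43,120,3,1,2.5,19,200,0
beef_stew,Beef stew,1.5 cup,350,420,28,6,8,32,880,12
fruit_cup,Mixed fruit cup,0.5 cup,125,70,0.5,0,0,18,5,30
cream_soup,Cream of chicken soup,1 cup,248,180,6,4,4,16,870,1
vanilla_pudding,Vanilla pudding,0.5 cup,140,150,3,2,1,26,180,0
apple_juice,Apple juice,180 mL,186,84,0,0,0,21,7,70
gelatin,Strawberry gelatin,0.5 cup,120,80,1.5,0,0,19,60,0
granola_bar,Granola bar (outside food),1 bar,42,190,4,2,5,28,105,0
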