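stratum,wg_group,rank,bns_group,mean_g,se
child,low_wg,1,Other breakfast cereal,6.4,0.6
child,low_wg,2,"Whole grain, oats, and high fibre breakfast cereals",6.4,0.9
child,low_wg,3,Whole grain and whole wheat bread,2.6,0.4
child,low_wg,4,Salty and high-fat snacks (including tortilla chips),1.2,0.1
child,low_wg,5,"Sweet snacks, sugar, candies",0.7,0.2
child,low_wg,6,"Rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",0.6,0.2
child,low_wg,7,Plain popcorn and pretzels,0.4,0.1
child,low_wg,8,Cereal grains and flours,0.3,0.1
child,low_wg,9,Crackers and crispbreads,0.2,0.1
child,low_wg,10,Rice,0.2,0.1
child,mid_wg,1,Whole grain and whole wheat bread,27.4,1.8
child,mid_wg,2,"Whole grain, oat, and high fibre breakfast cereal",10.8,1.1
child,mid_wg,3,"Rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",3.4,0.7
child,mid_wg,4,Other breakfast cereal,3.3,0.8
child,mid_wg,5,Rice,2.4,1.1
child,mid_wg,6,Salty and high-fat snacks (including tortilla chips),1.8,0.4
child,mid_wg,7,Pancakes and waffles,1.4,0.4
child,mid_wg,8,"Sweet snacks, sugar, candies",1.3,0.4
child,mid_wg,9,Cereal grains and flours,0.6,0.3
child,mid_wg,10,Granola bar,0.5,0.4
child,high_wg,1,"Whole grain, oat, and high fibre breakfast cereal",56.4,5.9
child,high_wg,2,Whole grain and whole wheat bread,38.7,2.6
child,high_wg,3,Rice,18.5,3.1
child,high_wg,4,"Rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",16.3,3.3
child,high_wg,5,Other breakfast cereal,6.6,1.5
child,high_wg,6,Salty and high-fat snacks (including tortilla chips),6.0,1.0
child,high_wg,7,Pasta,5.1,2.1
child,high_wg,8,Pancakes and waffles,3.9,1.5
child,high_wg,9,Cereal grains and flours,3.3,0.8
child,high_wg,10,"Sweet snacks, sugar, candies",2.1,0.6
adult,low_wg,1,"Whole grain, oat, and high fibre breakfast cereal",11.0,0.6
adult,low_wg,2,Whole grain and whole wheat bread,7.9,0.6
adult,low_wg,3,Other breakfast cereal,2.7,0.4
adult,low_wg,4,Salty and high-fat snacks (including tortilla chips),1.3,0.1
adult,low_wg,5,Crackers and crispbreads,1.1,0.3
adult,low_wg,6,"Rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",1.0,0.4
adult,low_wg,7,"Sweet snacks, sugar, candies",1.0,0.2
adult,low_wg,8,Granola bars,0.5,0.2
adult,low_wg,9,Muffins and English muffins,0.5,0.4
adult,low_wg,10,Cereal grains and flours,0.4,0.2
adult,mid_wg,1,Whole grain and whole wheat bread,40.3,1.6
adult,mid_wg,2,"Whole grain, oat, and high fibre breakfast cereal",15.1,1.8
adult,mid_wg,3,"Rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",4.9,1.1
adult,mid_wg,4,Rice,2.9,0.7
adult,mid_wg,5,Salty and high-fat snacks (including tortilla chips),1.9,0.4
adult,mid_wg,6,Other breakfast cereal,1.2,0.3
adult,mid_wg,7,Cereal grains and flours,1.1,0.4
adult,mid_wg,8,Pasta,0.7,0.3
adult,mid_wg,9,Other whole grain breads,0.7,0.2
adult,mid_wg,10,"Sweet snacks, sugar, candies",0.7,0.2
adult,high_wg,1,"Whole grain, oat, and high fibre breakfast cereal",89.8,12.4
adult,high_wg,2,Whole grain and whole wheat bread,45.5,2.8
adult,high_wg,3,Rice,35.8,9.2
adult,high_wg,4,"Rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",26.1,14.5
adult,high_wg,5,Cereal grains and flours,9.3,2.0
adult,high_wg,6,Pasta,4.3,1.2
adult,high_wg,7,Salty and high-fat snacks (including tortilla chips),2.1,0.5
adult,high_wg,8,Plain popcorn and pretzels,1.5,0.9
adult,high_wg,9,"Sweet snacks, sugar, candies",0.9,0.4
adult,high_wg,10,Muffins,0.9,0.4
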