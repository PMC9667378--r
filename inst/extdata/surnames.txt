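Martin
Bernard
Thomas
Petit
Robert
Richard
Durand
Dubois
Moreau
Laurent
Simon
Michel
Lefebvre
Leroy
Roux
David
Bertrand
Morel
Fournier
Girard
Bonnet
Dupont
Lambert
Fontaine
Rousseau
Vincent
Muller
Lefèvre
Faure
André
Mercier
Blanc
Guérin
Boyer
Garnier
Chevalier
François
Legrand
Gauthier
Garcia
Perrin
Robin
Clément
Morin
Nicolas
Henry
Roussel
Mathieu
Gautier
Masson
Marchand
Duval
Denis
Dumont
Marie
Lemaire
Noël
Meyer
Dufour
Meunier
Brun
Blanchard
Giraud
Joly
Rivière
Lucas
Brunet
Gaillard
Barbier
Arnaud
Martinez
Gérard
Roche
Renard
Schmitt
Roy
Leroux
Colin
Vidal
Caron
Picard
Roger
Fabre
Aubert
Lemoine
Renaud
Dumas
Lacroix
Olivier
Philippe
Bourgeois
Pierre
Benoît
Rey
Leclerc
Payet
Rolland
Leclercq
Guillaume
Lecomte
Lopez
Jean
Dupuy
Guillot
Hubert
Berger
Carpentier
Sanchez
Dupuis
Moulin
Louis
Deschamps
Huet
Vasseur
Perez
Boucher
Fleury
Royer
Klein
Jacquet
Adam
Paris
Poirier
Marty
Aubry
Guyot
Carré
Charles
Renault
Charpentier
Ménard
Maillard
Baron
Bertin
Bailly
Hervé
Schneider
Fernandez
Le Gall
Collet
Léger
Bouvier
Julien
Prévost
Millet
Perrot
Daniel
Le Roux
Cousin
Germain
Breton
Besson
Langlois
Rémy
Le Goff
Pelletier
Lévêque
Perrier
Leblanc
Barré
Lebrun
Marchal
Weber
Mallet
Hamon
Boulanger
Jacob
Monnier
Michaud
Rodriguez
Guichard
Gillet
Étienne
Grondin
Poulain
Tessier
Chevallier
Collin
Chauvin
Da Silva
Bouchet
Gay
Lemaître
Bénard
Maréchal
Humbert
Reynaud
Antoine
Hoarau
Perret
Barthélemy
Cordier
Pichon
Lejeune
Gilbert
Lamy
Delaunay
Pasquier
Carlier
Laporte
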