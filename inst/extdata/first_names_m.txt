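Jean
Pierre
Michel
André
Philippe
René
Louis
Alain
Jacques
Bernard
Marcel
Daniel
Roger
Robert
Paul
Claude
Christian
Henri
Georges
Nicolas
François
Antoine
Julien
Thomas
Maxime
Alexandre
Guillaume
Vincent
Olivier
Sébastien
Stéphane
Laurent
Pascal
Éric
Frédéric
Thierry
Bruno
Gérard
Didier
Patrick
Serge
Yves
Gilbert
Raymond
Lucien
Albert
Fernand
Émile
Gaston
Eugène
Léon
Maurice
Armand
Ernest
Gustave
Théodore
Benoît
Damien
Fabien
Gaël
Hervé
Cédric
Loïc
Matthieu
Romain
Tristan
Quentin
Bastien
Corentin
Erwan
Florian
Gauthier
Hugo
Baptiste
Jules
Léo
Mathis
Nathan
Raphaël
Samuel
Théo
Valentin
William
Xavier
Yann
Adrien
Arnaud
Aurélien
Clément
Cyril
Denis
Dominique
Édouard
Emmanuel
Fabrice
Franck
Grégoire
Jérôme
Joël
Lionel
Ludovic
Marc
Martin
Noël
Octave
Patrice
Régis
Rémi
Simon
Sylvain
Tanguy
Victor
Wilfried
Alban
Côme
Elouan
Josselin
Kilian
Malo
Nolan
Titouan
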